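#' Flag differentially expressed genes
#'
#' A gene is differentially expressed when its adjusted p-value is present
#' and `padj <= alpha_de` (inclusive boundary). The sign of the log2 fold
#' change gives the direction; a flagged gene with `log2fc == 0` is a
#' degenerate record and raises an error.
#'
#' @param de_table a `de_table` from [read_de_table()] (or a data.frame
#'   with `gene_id`, `log2fc`, `padj`).
#' @param alpha_de adjusted-p cutoff (default 0.1).
#' @return The table with added columns `de` (logical) and `direction`
#'   (`"up"`, `"down"`, or `NA` for non-DE genes).
#' @export
flag_degs <- function(de_table, alpha_de = 0.1) {
  de <- !is.na(de_table$padj) & de_table$padj <= alpha_de
  zero <- which(de & de_table$log2fc == 0)
  if (length(zero))
    stop("gene '", de_table$gene_id[zero[1]],
         "' flagged DE with log2fc = 0 (degenerate record)")
  de_table$de <- de
  de_table$direction <- ifelse(de, ifelse(de_table$log2fc > 0, "up", "down"),
                               NA_character_)
  de_table
}

#' Map DE flags onto families
#'
#' Counts, per family and species, the up- and down-regulated DEGs among
#' the family's member genes. DE genes that do not map to any family of
#' the Conserved Set are tallied as unassigned and excluded from all
#' statistics.
#'
#' @param conserved a `conserved_set`.
#' @param de_list named list (by species) of tables from [flag_degs()].
#' @return A `hog_de_flags` object: list of matrices `n_up`, `n_down`,
#'   `any_deg` (HOG x species) and a `summary` data.frame with per-species
#'   DEG totals, DEG-in-set totals, HOGs-with-DEG counts and unassigned
#'   DEG counts.
#' @export
hog_de_flags <- function(conserved, de_list) {
  stopifnot(inherits(conserved, "orthogroup_table"))
  species <- conserved$species
  missing <- setdiff(names(de_list), species)
  if (length(missing))
    stop("DE tables for unknown species: ", paste(missing, collapse = ", "))
  hog_ids <- conserved$hogs$hog_id
  dims <- list(hog_ids, species)
  n_up <- n_down <- matrix(0L, length(hog_ids), length(species), dimnames = dims)
  summ <- data.frame(species = species, n_deg = 0L, n_deg_in_set = 0L,
                     n_hogs_with_deg = 0L, n_unassigned = 0L,
                     stringsAsFactors = FALSE)
  for (sp in intersect(species, names(de_list))) {
    tab <- de_list[[sp]]
    degs <- tab[tab$de, , drop = FALSE]
    members <- conserved$genes[conserved$genes$species == sp, , drop = FALSE]
    idx <- match(degs$gene_id, members$gene_id)
    assigned <- !is.na(idx)
    hog_of <- members$hog_id[idx[assigned]]
    dir_of <- degs$direction[assigned]
    up_tab <- table(factor(hog_of[dir_of == "up"], levels = hog_ids))
    dn_tab <- table(factor(hog_of[dir_of == "down"], levels = hog_ids))
    n_up[, sp] <- as.integer(up_tab)
    n_down[, sp] <- as.integer(dn_tab)
    i <- match(sp, summ$species)
    summ$n_deg[i] <- nrow(degs)
    summ$n_deg_in_set[i] <- sum(assigned)
    summ$n_hogs_with_deg[i] <- sum(n_up[, sp] + n_down[, sp] >= 1L)
    summ$n_unassigned[i] <- sum(!assigned)
  }
  structure(list(n_up = n_up, n_down = n_down,
                 any_deg = (n_up + n_down) >= 1L, summary = summ),
            class = "hog_de_flags")
}

#' @export
print.hog_de_flags <- function(x, ...) {
  cat("hog_de_flags:", nrow(x$any_deg), "HOGs x", ncol(x$any_deg), "species\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify a family's regulation pattern
#'
#' Families with at least two DEGs (in the chosen scope) are classified as
#' `up` (all DEGs up-regulated), `down` (all down-regulated) or
#' `down_and_up` (both directions present); families with fewer than two
#' DEGs are `not_applicable`.
#'
#' @param de_flags a `hog_de_flags` object.
#' @param scope `"across_species"` pools all DEGs in the family over the
#'   given species; a single species name classifies within that species.
#' @param species species to pool over (defaults to all).
#' @return Factor (levels `up`, `down`, `down_and_up`, `not_applicable`),
#'   one element per HOG, named by hog id.
#' @export
regulation_category <- function(de_flags, scope = "across_species",
                                species = colnames(de_flags$n_up)) {
  if (!identical(scope, "across_species")) species <- scope
  stopifnot(all(species %in% colnames(de_flags$n_up)))
  up <- rowSums(de_flags$n_up[, species, drop = FALSE])
  dn <- rowSums(de_flags$n_down[, species, drop = FALSE])
  out <- rep("not_applicable", length(up))
  two <- up + dn >= 2
  out[two & dn == 0] <- "up"
  out[two & up == 0] <- "down"
  out[two & up >= 1 & dn >= 1] <- "down_and_up"
  factor(stats::setNames(out, rownames(de_flags$n_up)),
         levels = c("up", "down", "down_and_up", "not_applicable"))
}

#' Independence null for cross-species DE conservation
#'
#' From the per-species counts of families containing at least one DEG,
#' computes each species' success probability `p_s = s/N`, the product
#' probabilities `p_s4 = prod(p_s)` (a family has a DEG from every
#' species under independence) and `p_f4 = prod(1 - p_s)` (from none),
#' and the corresponding expected family counts. When observed counts are
#' supplied, each is compared to its expectation with a two-cell
#' chi-square goodness-of-fit test against `(p, 1-p)` (df = 1, no
#' continuity correction).
#'
#' @param n_hogs_with_deg named integer vector: per-species count of
#'   families with >= 1 DEG.
#' @param n_conserved total number of families in the Conserved Set.
#' @param observed_all,observed_none observed counts of families with a
#'   DEG from every / no species (optional).
#' @return List of class `conservation_stats`: `p_s`, `p_f`, `p_s4`,
#'   `p_f4`, `expected_all`, `expected_none`, and when observed counts are
#'   given, `observed_all`, `observed_none`, `chisq_all`, `chisq_none`
#'   (each `statistic`, `p_value`).
#' @examples
#' conservation_null(c(7434, 8866, 2865, 6956), 17488)
#' @export
conservation_null <- function(n_hogs_with_deg, n_conserved,
                              observed_all = NULL, observed_none = NULL) {
  if (n_conserved < 1) stop("empty Conserved Set")
  s <- n_hogs_with_deg
  if (any(s < 0 | s > n_conserved)) stop("counts must be in [0, N]")
  p_s <- s / n_conserved
  p_f <- 1 - p_s
  out <- list(n = n_conserved, p_s = p_s, p_f = p_f,
              p_s4 = prod(p_s), p_f4 = prod(p_f))
  out$expected_all <- out$p_s4 * n_conserved
  out$expected_none <- out$p_f4 * n_conserved
  gof <- function(obs, p) {
    if (p %in% c(0, 1)) return(list(statistic = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(
      stats::chisq.test(c(obs, n_conserved - obs), p = c(p, 1 - p)))
    list(statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  if (!is.null(observed_all)) {
    out$observed_all <- observed_all
    out$chisq_all <- gof(observed_all, out$p_s4)
  }
  if (!is.null(observed_none)) {
    out$observed_none <- observed_none
    out$chisq_none <- gof(observed_none, out$p_f4)
  }
  structure(out, class = "conservation_stats")
}

#' Conservation statistics from computed DE flags
#'
#' Convenience wrapper around [conservation_null()] taking the per-family
#' DE flags directly: observed counts are the families with a DEG from
#' every species and from none.
#'
#' @param de_flags a `hog_de_flags` object.
#' @return A `conservation_stats` list (see [conservation_null()]).
#' @export
conservation_stats <- function(de_flags) {
  m <- de_flags$any_deg
  conservation_null(colSums(m), nrow(m),
                    observed_all = sum(rowSums(m) == ncol(m)),
                    observed_none = sum(rowSums(m) == 0))
}

#' @export
print.conservation_stats <- function(x, ...) {
  cat("DE conservation vs independence null (N =", x$n, ")\n")
  cat("  p_s:", paste(sprintf("%s=%.4f", names(x$p_s), x$p_s), collapse = " "), "\n")
  cat(sprintf("  all-species: p_s4 = %.4f, expected = %.1f", x$p_s4, x$expected_all))
  if (!is.null(x$observed_all))
    cat(sprintf(", observed = %d, chi-sq p = %.3g",
                x$observed_all, x$chisq_all$p_value))
  cat("\n")
  cat(sprintf("  no-species:  p_f4 = %.4f, expected = %.1f", x$p_f4, x$expected_none))
  if (!is.null(x$observed_none))
    cat(sprintf(", observed = %d, chi-sq p = %.3g",
                x$observed_none, x$chisq_none$p_value))
  cat("\n")
  invisible(x)
}
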