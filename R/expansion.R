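#' Restrict to families conserved across all study species
#'
#' The Conserved Set is the subset of families with at least one gene from
#' every study species; it is the universe for every downstream statistic.
#' Families failing the filter are tallied by their pattern of absent
#' species (attribute `absence_report`).
#'
#' @param families an `orthogroup_table`.
#' @param species species that must all be present; defaults to the
#'   table's species.
#' @return A `conserved_set` (also an `orthogroup_table`) containing only
#'   conserved families, with attributes `absence_report` (data.frame
#'   `missing_species`, `n`) and `n_excluded`.
#' @export
filter_conserved <- function(families, species = families$species) {
  stopifnot(inherits(families, "orthogroup_table"))
  counts <- gene_counts(families)[, species, drop = FALSE]
  keep <- rowSums(counts >= 1L) == length(species)
  kept_ids <- families$hogs$hog_id[keep]

  absent <- counts[!keep, , drop = FALSE] == 0L
  pattern <- apply(absent, 1, function(z) paste(species[z], collapse = "+"))
  report <- if (length(pattern)) {
    tab <- table(pattern)
    data.frame(missing_species = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(missing_species = character(), n = integer())

  out <- new_orthogroup_table(
    families$genes[families$genes$hog_id %in% kept_ids, , drop = FALSE],
    families$hogs[keep, , drop = FALSE],
    families$species
  )
  class(out) <- c("conserved_set", class(out))
  attr(out, "absence_report") <- report
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @export
print.conserved_set <- function(x, ...) {
  cat("Conserved Set:", nrow(x$hogs), "HOGs (",
      attr(x, "n_excluded"), "families excluded )\n")
  invisible(x)
}

#' Ploidy-corrected gene count
#'
#' Scales a raw per-species copy number by `2 / ploidy` so polyploid
#' counts are comparable to the diploid baseline (a tetraploid's count is
#' halved).
#'
#' @param raw_count nonnegative integer count(s).
#' @param ploidy even integer >= 2.
#' @return `raw_count * 2 / ploidy`.
#' @examples
#' effective_count(4, 4) # 2
#' @export
effective_count <- function(raw_count, ploidy) {
  if (any(ploidy < 2)) stop("ploidy must be >= 2")
  if (any(raw_count < 0)) stop("raw_count must be nonnegative")
  raw_count * 2 / ploidy
}

#' Expansion call for one family
#'
#' A family is expanded in the focal species when its ploidy-corrected
#' count is at least `factor` times the ploidy-corrected count of *every*
#' background species (ties count as expanded: "at least twice"), and the
#' focal species carries at least `min_focal_copies` raw copies.
#'
#' Ploidy correction is symmetric: a polyploid's count is scaled by
#' `2/ploidy` whether it is focal or background.
#'
#' @param raw_counts named integer vector of raw per-species counts.
#' @param focal focal species name.
#' @param background character vector of background species.
#' @param config a [study_config()] supplying ploidies, `expansion_factor`
#'   and `min_focal_copies`.
#' @return Logical.
#' @export
is_expanded <- function(raw_counts, focal, background, config) {
  if (focal %in% background) stop("focal species in background set")
  pl <- ploidy_vector(config)
  eff <- effective_count(raw_counts[c(focal, background)],
                         pl[c(focal, background)])
  all(eff[focal] >= config$expansion_factor * eff[background]) &&
    raw_counts[focal] >= config$min_focal_copies
}

#' Expansion flags for every family and hypothesis
#'
#' Evaluates every configured hypothesis on every family of the Conserved
#' Set. For a multi-focal hypothesis the flag is the AND over its focal
#' species of the single-focal expansion call against the hypothesis'
#' background.
#'
#' @param conserved a `conserved_set`.
#' @param config a [study_config()] whose `hypotheses` define the columns.
#' @return Logical matrix, rows = HOGs (rownames = hog ids), columns =
#'   hypothesis ids. Attribute `counts` holds per-hypothesis totals.
#' @export
expansion_matrix <- function(conserved, config) {
  counts <- gene_counts(conserved)
  pl <- ploidy_vector(config)[colnames(counts)]
  eff <- sweep(counts, 2, pl / 2, "/")
  flags <- matrix(FALSE, nrow(counts), length(config$hypotheses),
                  dimnames = list(rownames(counts), names(config$hypotheses)))
  for (h in config$hypotheses) {
    fac <- if (is.null(h$factor)) config$expansion_factor else h$factor
    f <- rep(TRUE, nrow(counts))
    for (sp in h$focal) {
      ok <- counts[, sp] >= config$min_focal_copies
      for (bg in h$background)
        ok <- ok & (eff[, sp] >= fac * eff[, bg])
      f <- f & ok
    }
    flags[, h$id] <- f
  }
  structure(flags, counts = colSums(flags))
}
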