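#' Compose the nested candidate tiers
#'
#' For the phenotype class given by `group` (default `"tolerant"`) the
#' tiers are, per family of the Conserved Set:
#' \describe{
#'   \item{candidate}{expanded in *all* group species (the joint
#'     hypothesis) and differentially expressed in at least one group
#'     species;}
#'   \item{conserved_de}{additionally DE in *every* group species;}
#'   \item{unique_up}{additionally no DEG in any species of the opposite
#'     class and no down-regulated DEG from the group (all group DEGs
#'     up-regulated).}
#' }
#' Tiers are nested by construction: `unique_up` implies `conserved_de`
#' implies `candidate`. The symmetric contrast tiers arise from calling
#' the function with the opposite `group`. A stricter variant
#' `unique_up_min2` additionally requires at least two DEGs within each
#' group species; both are reported side by side.
#'
#' @param conserved the `conserved_set`.
#' @param expansion logical matrix from [expansion_matrix()]; must contain
#'   the joint hypothesis column for the group.
#' @param de_flags a `hog_de_flags` object.
#' @param config the [study_config()].
#' @param group `"tolerant"` or `"sensitive"`.
#' @return Data.frame of class `candidate_records`, one row per family:
#'   `hog_id`, per-species raw copy counts (`n_<species>`), per-hypothesis
#'   expansion flags (`expanded_<id>`), per-species DE flags
#'   (`deg_<species>`), `regulation` (pooled over all species),
#'   `regulation_group` (pooled over the group), and the tier flags.
#' @export
build_tiers <- function(conserved, expansion, de_flags, config,
                        group = c("tolerant", "sensitive")) {
  group <- match.arg(group)
  grp_sp <- species_of(config, group)
  opp_sp <- setdiff(config$species$name, grp_sp)
  joint <- if (length(grp_sp) > 2) paste0("all_", group) else paste0("both_", group)
  if (!joint %in% colnames(expansion))
    stop("expansion matrix lacks the joint hypothesis column '", joint, "'")

  hog_ids <- conserved$hogs$hog_id
  any_deg <- de_flags$any_deg[hog_ids, , drop = FALSE]
  expanded_joint <- expansion[hog_ids, joint]
  de_any_grp <- rowSums(any_deg[, grp_sp, drop = FALSE]) >= 1
  de_all_grp <- rowSums(any_deg[, grp_sp, drop = FALSE]) == length(grp_sp)
  de_any_opp <- rowSums(any_deg[, opp_sp, drop = FALSE]) >= 1
  grp_down <- rowSums(de_flags$n_down[hog_ids, grp_sp, drop = FALSE])

  candidate <- expanded_joint & de_any_grp
  conserved_de <- candidate & de_all_grp
  unique_up <- conserved_de & !de_any_opp & grp_down == 0
  min2_each <- rowSums((de_flags$n_up + de_flags$n_down)[hog_ids, grp_sp,
                                                         drop = FALSE] >= 2) ==
    length(grp_sp)
  unique_up_min2 <- unique_up & min2_each

  counts <- gene_counts(conserved)
  out <- data.frame(hog_id = hog_ids, stringsAsFactors = FALSE)
  for (sp in config$species$name) out[[paste0("n_", sp)]] <- counts[, sp]
  for (h in colnames(expansion))
    out[[paste0("expanded_", h)]] <- unname(expansion[hog_ids, h])
  for (sp in config$species$name)
    out[[paste0("deg_", sp)]] <- unname(any_deg[, sp])
  out$regulation <- as.character(regulation_category(de_flags))[
    match(hog_ids, rownames(de_flags$n_up))]
  out$regulation_group <- as.character(
    regulation_category(de_flags, species = grp_sp))[
      match(hog_ids, rownames(de_flags$n_up))]
  out$candidate <- unname(candidate)
  out$conserved_de <- unname(conserved_de)
  out$unique_up <- unname(unique_up)
  out$unique_up_min2 <- unname(unique_up_min2)
  structure(out, group = group, joint_hypothesis = joint,
            class = c("candidate_records", "data.frame"))
}

#' Tier sizes
#'
#' @param records a `candidate_records` data.frame.
#' @return Named integer vector of tier counts.
#' @export
tier_counts <- function(records) {
  c(candidate = sum(records$candidate),
    conserved_de = sum(records$conserved_de),
    unique_up = sum(records$unique_up),
    unique_up_min2 = sum(records$unique_up_min2))
}

#' Conserved-DE enrichment in the candidate tier
#'
#' Tests whether families of the candidate tier are enriched for DE in
#' *every* group species, against the universe of families DE in at least
#' one group species.
#'
#' @param records a `candidate_records` data.frame from [build_tiers()].
#' @param de_flags a `hog_de_flags` object.
#' @param config the [study_config()].
#' @return An `enrichment_result` with a `universe_definition` field.
#' @export
conserved_de_enrichment <- function(records, de_flags, config) {
  grp_sp <- species_of(config, attr(records, "group"))
  any_deg <- de_flags$any_deg[records$hog_id, grp_sp, drop = FALSE]
  universe <- records$hog_id[rowSums(any_deg) >= 1]
  property <- records$hog_id[rowSums(any_deg) == length(grp_sp)]
  res <- enrich(records$hog_id[records$candidate], property, universe, "over")
  res$universe_definition <- paste0("HOGs with DEG from >=1 ",
                                    attr(records, "group"), " species")
  res
}

#' Unique-DE enrichment in the conserved-DE tier
#'
#' Tests whether families of the conserved-DE tier are enriched for
#' having no DEG from any species of the opposite phenotype class,
#' against the universe of families DE in every group species.
#'
#' @inheritParams conserved_de_enrichment
#' @return An `enrichment_result` with a `universe_definition` field.
#' @export
unique_de_enrichment <- function(records, de_flags, config) {
  group <- attr(records, "group")
  grp_sp <- species_of(config, group)
  opp_sp <- setdiff(config$species$name, grp_sp)
  any_deg <- de_flags$any_deg[records$hog_id, , drop = FALSE]
  universe <- records$hog_id[
    rowSums(any_deg[, grp_sp, drop = FALSE]) == length(grp_sp)]
  property <- records$hog_id[
    rowSums(any_deg[, opp_sp, drop = FALSE]) == 0]
  res <- enrich(records$hog_id[records$conserved_de], property, universe, "over")
  res$universe_definition <- paste0("HOGs with DEG from every ", group,
                                    " species")
  res
}

#' Regulation-category enrichment
#'
#' One over-representation test per regulation category (`up`, `down`,
#' `down_and_up`) of a family subset against a universe, both restricted
#' to families with at least two DEGs (where the category is defined).
#'
#' @param subset_hogs character vector of family ids.
#' @param universe_hogs character vector of family ids.
#' @param regulation factor from [regulation_category()], named by hog id.
#' @return Data.frame with one row per category: `category`, `k`, `n`,
#'   `K`, `N`, `fold`, `p_value`.
#' @export
regulation_enrichment <- function(subset_hogs, universe_hogs, regulation) {
  applicable <- names(regulation)[regulation != "not_applicable"]
  uni <- intersect(universe_hogs, applicable)
  sub <- intersect(subset_hogs, applicable)
  rows <- lapply(c("up", "down", "down_and_up"), function(cat) {
    prop <- names(regulation)[regulation == cat]
    r <- enrich(sub, prop, uni, "over")
    ct <- r$contingency
    data.frame(category = cat, k = ct["k"], n = ct["n"], K = ct["K"],
               N = ct["N"], fold = r$fold, p_value = r$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
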