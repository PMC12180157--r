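#' Flag genes under diversifying selection
#'
#' Inclusive thresholding of the corrected branch-site-test p-values:
#' a gene is selected when it was tested and `p_corrected <= alpha_sel`.
#' Untested genes (those failing the alignment/tree quality filters of the
#' upstream selection workflow) are excluded from every denominator.
#'
#' @param selection_table a `selection_table` from
#'   [read_selection_table()].
#' @param alpha_sel corrected-p cutoff (default 0.05, inclusive).
#' @return The table with an added logical `selected` column, of class
#'   `selection_flags`.
#' @export
flag_selection <- function(selection_table, alpha_sel = 0.05) {
  p <- selection_table$p_corrected
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p_corrected outside [0,1]")
  selection_table$selected <- selection_table$tested & !is.na(p) & p <= alpha_sel
  class(selection_table) <- unique(c("selection_flags", class(selection_table)))
  selection_table
}

#' Per-species tested/selected tallies
#'
#' @param flags a `selection_flags` table.
#' @param conserved a `conserved_set` used to assign each gene to its
#'   species (genes are keyed per species; ids not found in the set are
#'   dropped from the tallies).
#' @return Data.frame `species`, `n_genes`, `n_tested`, `n_selected`.
#' @export
selection_summary <- function(flags, conserved) {
  genes <- conserved$genes
  idx <- match(genes$gene_id, flags$gene_id)
  tested <- !is.na(idx) & flags$tested[idx]
  selected <- !is.na(idx) & flags$selected[idx]
  agg <- function(v) as.integer(tapply(v, factor(genes$species,
                                                 levels = conserved$species), sum))
  data.frame(species = conserved$species,
             n_genes = as.integer(table(factor(genes$species,
                                               levels = conserved$species))),
             n_tested = agg(tested), n_selected = agg(selected),
             stringsAsFactors = FALSE)
}

# tested/selected lookups for a species' genes within the conserved set
species_gene_flags <- function(flags, conserved, species) {
  g <- conserved$genes[conserved$genes$species == species, , drop = FALSE]
  idx <- match(g$gene_id, flags$gene_id)
  data.frame(gene_id = g$gene_id, hog_id = g$hog_id,
             tested = !is.na(idx) & flags$tested[idx],
             selected = !is.na(idx) & flags$selected[idx],
             stringsAsFactors = FALSE)
}

#' Gene-level selection enrichment
#'
#' Tests whether a gene set of one species is enriched (or depleted) for
#' diversifying-selection signatures relative to a gene universe of the
#' same species. Both sets are restricted to *tested* genes before the
#' contingency is built, so the untested fraction biases neither side.
#'
#' @param gene_set character vector of gene ids (the foreground).
#' @param universe_genes character vector of gene ids (the background;
#'   must contain the foreground after restriction to tested genes).
#' @param flags a `selection_flags` table.
#' @param direction `"over"` or `"under"`.
#' @return An `enrichment_result` (see [enrich()]).
#' @export
selection_enrichment_genes <- function(gene_set, universe_genes, flags,
                                       direction = c("over", "under")) {
  direction <- match.arg(direction)
  tested <- flags$gene_id[flags$tested]
  selected <- flags$gene_id[flags$selected]
  uni <- intersect(universe_genes, tested)
  if (!length(uni)) stop("no tested genes in the universe")
  enrich(intersect(gene_set, tested), selected, uni, direction)
}

#' Family-level selection enrichment
#'
#' A family counts as a success when at least one DEG from the species
#' group is under diversifying selection, and as tested when at least one
#' such DEG was tested (families whose group DEGs were all untested drop
#' out of the sample). Two background conventions are available:
#' `"family"` uses the same family-level counting on the universe;
#' `"gene"` contrasts the family-level foreground proportion against the
#' gene-level selected/tested proportion among the group's DEGs in the
#' universe (the mixed convention used in the source tables; flagged in
#' the result metadata rather than resolved).
#'
#' @param hog_set character vector of family ids (foreground).
#' @param species_group character vector of species whose DEGs are
#'   considered.
#' @param flags a `selection_flags` table.
#' @param de_flags a `hog_de_flags` object (used with `conserved` to find
#'   each family's DEGs).
#' @param conserved the `conserved_set`.
#' @param de_list named list of flagged DE tables (from [flag_degs()]).
#' @param universe character vector of family ids (background).
#' @param convention `"family"` or `"gene"`.
#' @param direction `"over"` or `"under"`.
#' @return An `enrichment_result` with extra fields `convention` and
#'   `n_untested_hogs`.
#' @export
selection_enrichment_families <- function(hog_set, species_group, flags,
                                          de_flags, conserved, de_list,
                                          universe,
                                          convention = c("family", "gene"),
                                          direction = c("over", "under")) {
  convention <- match.arg(convention)
  direction <- match.arg(direction)

  deg_status <- deg_selection_status(species_group, flags, conserved, de_list)
  hog_status <- function(ids) {
    sub <- deg_status[deg_status$hog_id %in% ids, , drop = FALSE]
    tested_hogs <- unique(sub$hog_id[sub$tested])
    success_hogs <- unique(sub$hog_id[sub$selected])
    list(n = length(tested_hogs), k = length(success_hogs),
         untested = length(intersect(ids, unique(sub$hog_id))) - length(tested_hogs))
  }
  fg <- hog_status(hog_set)
  if (convention == "family") {
    bg <- hog_status(universe)
    res <- enrich_counts(fg$k, fg$n, bg$k, bg$n, direction)
  } else {
    in_uni <- deg_status[deg_status$hog_id %in% universe & deg_status$tested, ,
                         drop = FALSE]
    res <- enrich_counts(fg$k, fg$n, sum(in_uni$selected), nrow(in_uni),
                         direction)
  }
  res$convention <- convention
  res$n_untested_hogs <- fg$untested
  res
}

# one row per DEG of the group mapped into the conserved set
deg_selection_status <- function(species_group, flags, conserved, de_list) {
  rows <- lapply(species_group, function(sp) {
    sg <- species_gene_flags(flags, conserved, sp)
    degs <- de_list[[sp]]$gene_id[de_list[[sp]]$de]
    sg[sg$gene_id %in% degs, c("hog_id", "gene_id", "tested", "selected"),
       drop = FALSE]
  })
  do.call(rbind, rows)
}

#' Selection-enrichment report tables
#'
#' Runs the three standard gene-level designs for every species:
#' (a) DEGs vs all genes of the species in the Conserved Set
#' (under-representation), (b) genes in species-specific expanded families
#' vs all genes (over-representation), and (c) DEGs in expanded families
#' vs all DEGs (over-representation). All denominators count tested genes
#' only.
#'
#' @param conserved the `conserved_set`.
#' @param expansion logical matrix from [expansion_matrix()].
#' @param de_list named list of flagged DE tables.
#' @param flags a `selection_flags` table.
#' @param config the [study_config()].
#' @return Named list of data.frames `degs_vs_all`, `expanded_vs_all`,
#'   `degs_in_expanded_vs_degs`, each with one row per species and columns
#'   `species`, `hypothesis`, `k`, `n`, `K`, `N`, `percent_set`,
#'   `percent_background`, `direction`, `p_value`.
#' @export
selection_report_tables <- function(conserved, expansion, de_list, flags,
                                    config) {
  per_species <- function(design) {
    rows <- lapply(config$species$name, function(sp) {
      if (!sp %in% colnames(expansion) && design != "a") return(NULL)
      sg <- species_gene_flags(flags, conserved, sp)
      degs <- if (sp %in% names(de_list))
        de_list[[sp]]$gene_id[de_list[[sp]]$de] else character()
      exp_hogs <- rownames(expansion)[expansion[, sp]]
      in_exp <- sg$gene_id[sg$hog_id %in% exp_hogs]
      spec <- switch(design,
        a = list(set = intersect(sg$gene_id, degs), uni = sg$gene_id,
                 dir = "under"),
        b = list(set = in_exp, uni = sg$gene_id, dir = "over"),
        c = list(set = intersect(in_exp, degs),
                 uni = intersect(sg$gene_id, degs), dir = "over"))
      r <- selection_enrichment_genes(spec$set, spec$uni, flags, spec$dir)
      ct <- r$contingency
      data.frame(species = sp, hypothesis = if (design == "a") NA_character_ else sp,
                 k = ct["k"], n = ct["n"], K = ct["K"], N = ct["N"],
                 percent_set = 100 * ct["k"] / max(ct["n"], 1),
                 percent_background = 100 * ct["K"] / max(ct["N"], 1),
                 direction = spec$dir, p_value = r$p_value,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
  }
  list(degs_vs_all = per_species("a"),
       expanded_vs_all = per_species("b"),
       degs_in_expanded_vs_degs = per_species("c"))
}
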