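#' Run the full prioritization analysis
#'
#' Orchestrates the pipeline: Conserved-Set filtering, ploidy-corrected
#' expansion calling for every hypothesis, DE flagging and family
#' mapping, regulation classification, the DE-conservation null, the
#' expansion-by-DE enrichment battery, candidate tiers with their
#' enrichments (plus the phenotype-swapped contrast tiers), and — when
#' the corresponding inputs are given — the selection-enrichment tables
#' and GO over-representation of the candidate tiers.
#'
#' @param orthogroups an `orthogroup_table` from [read_orthogroups()].
#' @param de_tables named list of `de_table`s, one per study species.
#' @param config a [study_config()].
#' @param selection optional `selection_table`.
#' @param go_map optional annotation map from [read_go_map()].
#' @param out_dir optional directory; when given, result tables and a
#'   YAML manifest are written (see [write_run_outputs()]).
#' @return A `study_run`: list with `config`, `conserved`, `expansion`,
#'   `de_list`, `de_flags`, `regulation`, `conservation`, `battery`,
#'   `tiers` (records + counts per phenotype group and the tier
#'   enrichments), `regulation_tests`, `selection`, `go`, and `manifest`.
#' @export
run_study <- function(orthogroups, de_tables, config, selection = NULL,
                      go_map = NULL, out_dir = NULL) {
  missing_sp <- setdiff(config$species$name, names(de_tables))
  if (length(missing_sp))
    stop("no DE table for species: ", paste(missing_sp, collapse = ", "))

  conserved <- filter_conserved(orthogroups, config$species$name)
  if (nrow(conserved$hogs) == 0) stop("empty Conserved Set")
  expansion <- expansion_matrix(conserved, config)
  de_list <- lapply(de_tables[config$species$name], flag_degs,
                    alpha_de = config$alpha_de)
  de_flags <- hog_de_flags(conserved, de_list)
  regulation <- regulation_category(de_flags)
  conservation <- conservation_stats(de_flags)

  battery <- expansion_de_battery(conserved, expansion, de_flags, config)
  regulation_tests <- regulation_battery(conserved, expansion, de_flags,
                                         regulation, config)

  tiers <- list()
  for (group in c("tolerant", "sensitive")) {
    rec <- build_tiers(conserved, expansion, de_flags, config, group)
    tiers[[group]] <- list(
      records = rec, counts = tier_counts(rec),
      conserved_de = conserved_de_enrichment(rec, de_flags, config),
      unique_de = unique_de_enrichment(rec, de_flags, config))
  }

  sel_out <- NULL
  if (!is.null(selection)) {
    flags <- flag_selection(selection, config$alpha_sel)
    sel_out <- list(
      flags = flags,
      summary = selection_summary(flags, conserved),
      tables = selection_report_tables(conserved, expansion, de_list,
                                       flags, config))
    for (group in c("tolerant", "sensitive")) {
      grp_sp <- species_of(config, group)
      cand <- tiers[[group]]$records
      sel_out[[paste0("candidates_", group)]] <- lapply(
        c(family = "family", gene = "gene"), function(conv)
          selection_enrichment_families(
            cand$hog_id[cand$candidate], grp_sp, flags, de_flags,
            conserved, de_list, universe = conserved$hogs$hog_id,
            convention = conv, direction = "over"))
    }
  }

  go_out <- NULL
  if (!is.null(go_map)) {
    ann <- union_annotate(conserved, go_map)
    rec <- tiers$tolerant$records
    go_out <- list(
      annotation = ann,
      candidate = go_over_representation(rec$hog_id[rec$candidate],
                                         conserved$hogs$hog_id, ann),
      conserved_de = go_over_representation(rec$hog_id[rec$conserved_de],
                                            conserved$hogs$hog_id, ann))
  }

  run <- structure(list(
    config = config, conserved = conserved, expansion = expansion,
    de_list = de_list, de_flags = de_flags, regulation = regulation,
    conservation = conservation, battery = battery,
    regulation_tests = regulation_tests, tiers = tiers,
    selection = sel_out, go = go_out), class = "study_run")
  run$manifest <- build_manifest(run)
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# Expansion-by-DE enrichment battery: for every hypothesis, the expanded
# families against the whole Conserved Set, with the DE property matched
# to the hypothesis (per-focal-species DE for single-focal hypotheses;
# any-focal and all-focal DE for joint ones).
expansion_de_battery <- function(conserved, expansion, de_flags, config) {
  universe <- conserved$hogs$hog_id
  any_deg <- de_flags$any_deg
  rows <- list()
  for (h in config$hypotheses) {
    subset <- rownames(expansion)[expansion[, h$id]]
    props <- if (length(h$focal) == 1L) {
      list(deg = universe[any_deg[, h$focal] >= 1])
    } else {
      list(deg_any = universe[rowSums(any_deg[, h$focal, drop = FALSE]) >= 1],
           deg_all = universe[rowSums(any_deg[, h$focal, drop = FALSE]) ==
                                length(h$focal)])
    }
    for (pn in names(props)) {
      r <- enrich(subset, props[[pn]], universe, "over")
      ct <- r$contingency
      rows[[length(rows) + 1L]] <- data.frame(
        test_id = paste0(h$id, ":", pn),
        hypothesis = h$id, property = pn,
        universe = "conserved_set",
        k = ct["k"], n = ct["n"], K = ct["K"], N = ct["N"],
        fold = r$fold, p_value = r$p_value,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

# Regulation-category enrichment per hypothesis: expanded families with a
# DEG from every focal species against all families with such DEGs,
# categories pooled over all species (families with >= 2 DEGs).
regulation_battery <- function(conserved, expansion, de_flags, regulation,
                               config) {
  universe_all <- conserved$hogs$hog_id
  rows <- list()
  for (h in config$hypotheses) {
    de_focal <- rowSums(de_flags$any_deg[, h$focal, drop = FALSE]) ==
      length(h$focal)
    universe <- universe_all[de_focal]
    subset <- intersect(rownames(expansion)[expansion[, h$id]], universe)
    res <- regulation_enrichment(subset, universe, regulation)
    res$hypothesis <- h$id
    rows[[length(rows) + 1L]] <- res[, c("hypothesis", "category", "k", "n",
                                         "K", "N", "fold", "p_value")]
  }
  do.call(rbind, rows)
}

build_manifest <- function(run) {
  cs <- run$conservation
  ver <- tryCatch(as.character(utils::packageVersion("expanDE")),
                  error = function(e) NA_character_)
  list(
    tool_version = ver,
    species = run$config$species,
    thresholds = list(alpha_de = run$config$alpha_de,
                      alpha_sel = run$config$alpha_sel,
                      expansion_factor = run$config$expansion_factor,
                      min_focal_copies = run$config$min_focal_copies),
    stage_counts = list(
      n_hogs_input = nrow(run$conserved$hogs) + attr(run$conserved, "n_excluded"),
      n_conserved = nrow(run$conserved$hogs),
      n_genes_conserved = nrow(run$conserved$genes),
      expansion = as.list(attr(run$expansion, "counts")),
      de_summary = run$de_flags$summary),
    conservation = list(
      p_s = as.list(cs$p_s), p_s4 = cs$p_s4, p_f4 = cs$p_f4,
      expected_all = cs$expected_all, expected_none = cs$expected_none,
      observed_all = cs$observed_all, observed_none = cs$observed_none,
      chisq_all_p = cs$chisq_all$p_value,
      chisq_none_p = cs$chisq_none$p_value),
    battery = run$battery,
    tiers = lapply(run$tiers, function(t) list(
      counts = as.list(t$counts),
      conserved_de = enrichment_row(t$conserved_de),
      unique_de = enrichment_row(t$unique_de)))
  )
}

enrichment_row <- function(r) {
  c(as.list(r$contingency),
    list(direction = r$direction, p_value = r$p_value, fold = r$fold,
         universe = r$universe_definition))
}

#' Write the result tables and manifest of a run
#'
#' Writes, deterministically (UTF-8, tabs, LF): the candidate table and
#' its sensitive-group contrast, the expansion flag matrix, the
#' enrichment battery, the regulation tests, a DE-conservation report,
#' the selection tables and GO results when available, and
#' `manifest.yaml`.
#'
#' @param run a `study_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir` invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_candidate_table(run$tiers$tolerant$records, p("candidates.tsv"))
  write_candidate_table(run$tiers$sensitive$records, p("contrast_sensitive.tsv"))
  em <- data.frame(hog_id = rownames(run$expansion),
                   run$expansion * 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_lf(em, p("expansion_matrix.tsv"))
  write_tsv_lf(run$battery, p("enrichment_battery.tsv"))
  write_tsv_lf(run$regulation_tests, p("regulation_tests.tsv"))
  con <- file(p("conservation_report.txt"), "wb")
  sink(con); print(run$conservation); sink()
  close(con)
  if (!is.null(run$selection)) {
    write_tsv_lf(run$selection$summary, p("selection_summary.tsv"))
    for (nm in names(run$selection$tables))
      write_tsv_lf(run$selection$tables[[nm]],
                   p(paste0("selection_", nm, ".tsv")))
  }
  if (!is.null(run$go)) {
    write_tsv_lf(run$go$candidate, p("go_candidates.tsv"))
    write_tsv_lf(run$go$conserved_de, p("go_conserved_de.tsv"))
  }
  yaml::write_yaml(manifest_serializable(run$manifest), p("manifest.yaml"))
  invisible(out_dir)
}

manifest_serializable <- function(m) {
  m$battery <- lapply(seq_len(nrow(m$battery)), function(i)
    as.list(m$battery[i, ]))
  sc <- m$stage_counts
  sc$de_summary <- lapply(seq_len(nrow(sc$de_summary)), function(i)
    as.list(sc$de_summary[i, ]))
  m$stage_counts <- sc
  m$species <- lapply(seq_len(nrow(m$species)), function(i)
    as.list(m$species[i, ]))
  m
}

#' Human-readable run summary
#'
#' Formats the manifest of a run as text: per-species DEG and family
#' counts, expansion counts per hypothesis, the conservation statistics,
#' tier counts and every enrichment p-value with its universe. Every
#' number is taken from the manifest; nothing is recomputed.
#'
#' @param run a `study_run`.
#' @return Character vector of lines, invisibly; printed to the console.
#' @export
report_study <- function(run) {
  m <- run$manifest
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== Candidate prioritization run (expanDE %s) ==", m$tool_version)
  add("Conserved Set: %d of %d families", m$stage_counts$n_conserved,
      m$stage_counts$n_hogs_input)
  ds <- m$stage_counts$de_summary
  for (i in seq_len(nrow(ds)))
    add("  %s: %d DEGs in set, %d families with DEG", ds$species[i],
        ds$n_deg_in_set[i], ds$n_hogs_with_deg[i])
  add("Expansions per hypothesis:")
  for (h in names(m$stage_counts$expansion))
    add("  %s: %d", h, m$stage_counts$expansion[[h]])
  cv <- m$conservation
  add("DE conservation: p_s4 = %.4f (expected %.1f, observed %d); p_f4 = %.4f (expected %.1f, observed %d)",
      cv$p_s4, cv$expected_all, cv$observed_all,
      cv$p_f4, cv$expected_none, cv$observed_none)
  add("Expansion x DE battery:")
  b <- m$battery
  for (i in seq_len(nrow(b)))
    add("  %s: %d/%d vs %d/%d, p = %.3g", b$test_id[i], b$k[i], b$n[i],
        b$K[i], b$N[i], b$p_value[i])
  for (g in names(m$tiers)) {
    t <- m$tiers[[g]]
    add("%s tiers: candidate = %d, conserved_de = %d, unique_up = %d",
        g, t$counts$candidate, t$counts$conserved_de, t$counts$unique_up)
    if (t$counts$candidate == 0)
      add("  (no family is expanded in all %s species and DE in any of them)", g)
    add("  conserved-DE enrichment: %d/%d vs %d/%d, p = %.3g [%s]",
        t$conserved_de$k, t$conserved_de$n, t$conserved_de$K,
        t$conserved_de$N, t$conserved_de$p_value, t$conserved_de$universe)
    add("  unique-DE enrichment: %d/%d vs %d/%d, p = %.3g [%s]",
        t$unique_de$k, t$unique_de$n, t$unique_de$K, t$unique_de$N,
        t$unique_de$p_value, t$unique_de$universe)
  }
  cat(ln, sep = "\n")
  invisible(ln)
}

#' @export
print.study_run <- function(x, ...) {
  report_study(x)
  invisible(x)
}
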