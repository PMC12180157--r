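#' Configuration for the synthetic study generator
#'
#' Describes the statistical structure of a synthetic four-species study:
#' heavy-tailed per-species family sizes, planted trait-specific
#' expansions, per-species DE probabilities with a cross-species
#' conservation coupling and an expansion-DE association, signed
#' regulation, selection flags enriched in chosen subsets, and a flat GO
#' annotation with one planted term.
#'
#' Defaults emulate the study conditions of a two-tolerant /
#' two-sensitive Brassicaceae panel with one tetraploid sensitive
#' species: per-species gene-level DE rates near the observed leaf
#' drought-response rates, strong cross-species DE conservation, and a
#' mild excess of DE among duplicated genes.
#'
#' @param config a [study_config()]; the default is two tolerant
#'   diploids, one sensitive diploid and one sensitive tetraploid.
#' @param n_hogs number of families to generate.
#' @param family_q geometric parameter of the per-species copy-number law
#'   (copies = 1 + Geometric(`family_q`); a tetraploid draws two such
#'   subgenome counts and sums them).
#' @param absence_rate probability that a species is absent from a family
#'   (family then drops out of the Conserved Set).
#' @param expansion_rates named vector of planting rates, one per
#'   hypothesis id; must sum to < 1.
#' @param de_base_rate named per-species marginal probability that a gene
#'   is differentially expressed.
#' @param conservation_coupling odds multiplier (>= 1) applied to every
#'   gene of a "drought-responsive" family; induces cross-species DE
#'   co-occurrence. 1 disables the coupling.
#' @param responsive_rate fraction of families that are
#'   drought-responsive (the latent coupling indicator).
#' @param expansion_de_multiplier DE odds multiplier (>= 1) for genes of a
#'   focal species in a family planted as expanded.
#' @param up_fraction probability that a DEG is up-regulated.
#' @param up_fraction_expanded the same for DEGs of a tolerant focal
#'   species in planted tolerant expansions.
#' @param na_padj_rate fraction of non-DE genes with missing adjusted p
#'   (independent-filtering convention).
#' @param tested_rate probability a gene passed the selection-workflow
#'   quality filters.
#' @param base_selected_rate probability a tested gene shows a
#'   diversifying-selection signature.
#' @param selection_de_multiplier multiplier (>= 1) on that probability
#'   for DEGs in planted tolerant expansions (capped at 1).
#' @param go_n_terms,go_lambda number of GO terms and the Poisson mean of
#'   terms per gene.
#' @param go_planted_term,go_planted_rate term added with the given
#'   probability to genes of planted tolerant-joint expansions.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    config = study_config(
      species   = c("tolA", "tolB", "senA", "senB"),
      ploidy    = c(2, 2, 2, 4),
      phenotype = c("tolerant", "tolerant", "sensitive", "sensitive")),
    n_hogs = 2000,
    family_q = 0.7,
    absence_rate = 0.05,
    expansion_rates = NULL,
    de_base_rate = NULL,
    conservation_coupling = 4,
    responsive_rate = 0.3,
    expansion_de_multiplier = 2,
    up_fraction = 0.5,
    up_fraction_expanded = 0.8,
    na_padj_rate = 0.05,
    tested_rate = 0.72,
    base_selected_rate = 0.095,
    selection_de_multiplier = 2,
    go_n_terms = 50,
    go_lambda = 2,
    go_planted_term = "GO:0000001",
    go_planted_rate = 0.3) {
  sp <- config$species$name
  if (is.null(de_base_rate)) {
    de_base_rate <- stats::setNames(rep(0.3, length(sp)), sp)
    if (length(sp) == 4) de_base_rate[] <- c(0.39, 0.45, 0.16, 0.26)
  }
  if (is.null(expansion_rates)) {
    ids <- names(config$hypotheses)
    expansion_rates <- stats::setNames(
      ifelse(vapply(config$hypotheses, function(h) length(h$focal), 0L) > 1,
             0.01, 0.03), ids)
  }
  stopifnot(all(names(de_base_rate) %in% sp),
            all(names(expansion_rates) %in% names(config$hypotheses)))
  if (sum(expansion_rates) >= 1)
    stop("infeasible planting: expansion rates sum to >= 1")
  if (conservation_coupling < 1 || expansion_de_multiplier < 1 ||
      selection_de_multiplier < 1)
    stop("multipliers must be >= 1")
  probs <- c(absence_rate, de_base_rate, responsive_rate, up_fraction,
             up_fraction_expanded, na_padj_rate, tested_rate,
             base_selected_rate, go_planted_rate, expansion_rates)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  structure(as.list(environment()), class = "synthetic_config")
}

# Family-size-compensated DE probabilities. A gene in a family with c
# copies of its species gets per-gene probability p(c) = 1 - (1-F)^(1/c),
# so that under null settings the family-level probability of containing
# a DEG equals F for every family regardless of copy number (family-level
# DE independent of expansion status), while the expected DEG count per
# family stays near -log(1-F). The family-level rate F is calibrated so
# the gene-level marginal matches de_base_rate given the responsive-HOG
# coupling:  sum_i c_i * E_z[sig(odds(p(c_i)) * coupling^z)] / sum_i c_i.
calibrate_family_rate <- function(rate, copies, rho, coupling) {
  copies <- copies[copies > 0]
  if (rate <= 0) return(0)
  if (rate >= 1) return(1)
  sig <- function(o) o / (1 + o)
  marginal <- function(F) {
    p0 <- 1 - (1 - F)^(1 / copies)
    o <- p0 / (1 - p0)
    per_gene <- rho * sig(o * coupling) + (1 - rho) * sig(o)
    sum(copies * per_gene) / sum(copies)
  }
  stats::uniroot(function(F) marginal(F) - rate,
                 c(1e-12, 1 - 1e-9), tol = 1e-12)$root
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline reads — orthogroup table, per-species
#' DE tables, selection table, GO map — plus a truth record of every
#' planted flag, all reproducible from the seed (identical seed and
#' configuration yield byte-identical files when `dir` is given).
#'
#' @param sim a [synthetic_config()].
#' @param seed integer seed for all randomness.
#' @param dir optional directory; when given, all tables are written as
#'   TSVs in the exact dialects the readers expect, plus `truth_hogs.tsv`,
#'   `truth_genes.tsv` and `config.yaml`.
#' @return List of class `synthetic_study`: `orthogroups`
#'   (an `orthogroup_table`), `de_tables` (named list of `de_table`),
#'   `selection` (a `selection_table`), `go_map`, `truth` (list `hogs`,
#'   `genes`), `config` (the `study_config`), `sim`, `seed`.
#' @export
generate_study <- function(sim, seed, dir = NULL) {
  stopifnot(inherits(sim, "synthetic_config"))
  set.seed(as.integer(seed))
  cfg <- sim$config
  sp <- cfg$species$name
  pl <- ploidy_vector(cfg)
  n <- sim$n_hogs
  hog_ids <- sprintf("H%06d", seq_len(n))

  # per-species copy counts: 1 + geometric per subgenome, absence knockout
  counts <- matrix(0L, n, length(sp), dimnames = list(hog_ids, sp))
  for (s in sp) {
    sub <- pl[s] %/% 2L
    draws <- matrix(1L + stats::rgeom(n * sub, sim$family_q), n, sub)
    x <- as.integer(rowSums(draws))
    x[stats::runif(n) < sim$absence_rate] <- 0L
    counts[, s] <- x
  }

  # plant expansion patterns
  ids <- names(sim$expansion_rates)
  pattern <- sample(c("none", ids), n, replace = TRUE,
                    prob = c(1 - sum(sim$expansion_rates), sim$expansion_rates))
  for (hid in ids) {
    h <- cfg$hypotheses[[hid]]
    rows <- which(pattern == hid)
    if (!length(rows)) next
    counts[rows, ][counts[rows, , drop = FALSE] == 0L] <- 1L
    for (f in h$focal) {
      bg_eff <- sweep(counts[rows, h$background, drop = FALSE], 2,
                      pl[h$background] / 2, "/")
      need <- ceiling(cfg$expansion_factor * apply(bg_eff, 1, max) * pl[f] / 2)
      planted <- pmax(cfg$min_focal_copies, need, counts[rows, f])
      if (any(planted > 10 * (1 + 1 / sim$family_q) * max(pl)))
        stop("infeasible planting: required focal copy number (",
             max(planted), ") far exceeds the family-size law")
      counts[rows, f] <- as.integer(planted)
    }
  }

  conserved_flag <- rowSums(counts >= 1L) == length(sp)

  # gene table (copies = the family's copy number for the gene's species)
  gene_rows <- lapply(sp, function(s) {
    reps <- counts[, s]
    data.frame(hog_id = rep(hog_ids, reps),
               species = rep(s, sum(reps)),
               gene_id = paste0(s, "_", rep(hog_ids, reps), "_g",
                                sequence(reps)),
               copies = rep(reps, reps),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_rows)
  genes$pattern <- pattern[match(genes$hog_id, hog_ids)]
  focal_of <- lapply(cfg$hypotheses, `[[`, "focal")
  genes$focal <- FALSE
  for (hid in ids)
    genes$focal[genes$pattern == hid &
                  genes$species %in% focal_of[[hid]]] <- TRUE

  # DE assignment: per-gene Bernoulli, family-size compensated, with
  # HOG-level couplings acting on the odds scale
  responsive <- stats::runif(n) < sim$responsive_rate
  genes$responsive <- responsive[match(genes$hog_id, hog_ids)]
  fam_rate <- vapply(sp, function(s)
    calibrate_family_rate(sim$de_base_rate[s], counts[, s],
                          sim$responsive_rate, sim$conservation_coupling), 0)
  p0 <- 1 - (1 - fam_rate[genes$species])^(1 / genes$copies)
  o <- p0 / (1 - p0)
  o <- o * ifelse(genes$responsive, sim$conservation_coupling, 1)
  o <- o * ifelse(genes$focal, sim$expansion_de_multiplier, 1)
  genes$de <- stats::runif(nrow(genes)) < 1 - 1 / (1 + o)

  tol_sp <- species_of(cfg, "tolerant")
  p_up <- ifelse(genes$focal & genes$species %in% tol_sp,
                 sim$up_fraction_expanded, sim$up_fraction)
  genes$direction <- ifelse(genes$de,
                            ifelse(stats::runif(nrow(genes)) < p_up, "up", "down"),
                            NA_character_)

  # DE tables: padj uniform below/above the cutoff, lognormal magnitudes
  ng <- nrow(genes)
  padj <- ifelse(genes$de,
                 stats::runif(ng, 0, 1) * cfg$alpha_de,
                 cfg$alpha_de + stats::runif(ng, 0, 1) * (1 - cfg$alpha_de))
  padj[!genes$de & stats::runif(ng) < sim$na_padj_rate] <- NA_real_
  mag <- stats::rlnorm(ng, meanlog = 0, sdlog = 0.6)
  sign_nonde <- sample(c(-1, 1), ng, replace = TRUE)
  l2fc <- ifelse(genes$de, ifelse(genes$direction == "up", mag, -mag),
                 sign_nonde * mag * 0.3)
  base_mean <- round(stats::rlnorm(ng, meanlog = 5, sdlog = 1.5), 3)
  de_tables <- lapply(sp, function(s) {
    i <- genes$species == s
    structure(data.frame(gene_id = genes$gene_id[i],
                         log2fc = round(l2fc[i], 4),
                         padj = padj[i],
                         base_mean = base_mean[i],
                         stringsAsFactors = FALSE),
              species = s, class = c("de_table", "data.frame"))
  })
  names(de_tables) <- sp

  # selection flags: enriched among DEGs in planted tolerant expansions
  tested <- stats::runif(ng) < sim$tested_rate
  tol_focal_deg <- genes$de & genes$focal & genes$species %in% tol_sp
  p_sel <- pmin(1, sim$base_selected_rate *
                  ifelse(tol_focal_deg, sim$selection_de_multiplier, 1))
  selected <- tested & stats::runif(ng) < p_sel
  p_corr <- rep(NA_real_, ng)
  p_corr[tested] <- ifelse(selected[tested],
                           stats::runif(sum(tested)) * cfg$alpha_sel,
                           cfg$alpha_sel + stats::runif(sum(tested)) *
                             (1 - cfg$alpha_sel))[seq_len(sum(tested))]
  selection <- structure(
    data.frame(gene_id = genes$gene_id, p_corrected = p_corr,
               tested = tested, stringsAsFactors = FALSE),
    class = c("selection_table", "data.frame"))

  # GO map: Poisson terms per gene, planted term in tolerant-joint families
  terms <- sprintf("GO:%07d", seq_len(sim$go_n_terms))
  k_terms <- stats::rpois(ng, sim$go_lambda)
  k_terms <- pmin(k_terms, sim$go_n_terms)
  drawn <- lapply(k_terms, function(k) sample(terms, k))
  joint_tol <- names(cfg$hypotheses)[vapply(cfg$hypotheses, function(h)
    setequal(h$focal, tol_sp), TRUE)]
  in_planted_joint <- genes$pattern %in% joint_tol
  add <- in_planted_joint & stats::runif(ng) < sim$go_planted_rate
  drawn[add] <- lapply(drawn[add], function(x)
    unique(c(x, sim$go_planted_term)))
  go_map <- data.frame(gene_id = genes$gene_id, species = genes$species,
                       go_terms = vapply(drawn, paste, "", collapse = ", "),
                       stringsAsFactors = FALSE)

  orthogroups <- new_orthogroup_table(
    genes[, c("hog_id", "species", "gene_id")],
    data.frame(hog_id = hog_ids, og_id = NA_character_,
               stringsAsFactors = FALSE),
    sp)

  truth_hogs <- data.frame(hog_id = hog_ids, pattern = pattern,
                           conserved = conserved_flag,
                           responsive = responsive,
                           stringsAsFactors = FALSE)
  for (s in sp) truth_hogs[[paste0("n_", s)]] <- counts[, s]
  truth_genes <- genes[, c("gene_id", "species", "hog_id", "de", "direction")]
  truth_genes$tested <- tested
  truth_genes$selected <- selected

  study <- structure(list(orthogroups = orthogroups, de_tables = de_tables,
                          selection = selection, go_map = go_map,
                          truth = list(hogs = truth_hogs, genes = truth_genes),
                          config = cfg, sim = sim, seed = as.integer(seed)),
                     class = "synthetic_study")
  if (!is.null(dir)) write_synthetic_study(study, dir)
  study
}

#' Write a synthetic study to a directory of standard-dialect TSVs
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_orthogroups(study$orthogroups, p("orthogroups.tsv"))
  for (s in names(study$de_tables)) {
    df <- study$de_tables[[s]]
    names(df) <- c("gene", "log2FoldChange", "padj", "baseMean")
    write_tsv_lf(df, p(paste0("de_", s, ".tsv")))
  }
  sel <- study$selection
  names(sel) <- c("gene", "p_corrected", "tested")
  sel$tested <- as.integer(sel$tested)
  write_tsv_lf(sel, p("selection.tsv"))
  names(study$go_map) <- c("gene", "species", "go_terms")
  write_tsv_lf(study$go_map, p("go_map.tsv"))
  th <- study$truth$hogs
  th$conserved <- as.integer(th$conserved)
  th$responsive <- as.integer(th$responsive)
  write_tsv_lf(th, p("truth_hogs.tsv"))
  tg <- study$truth$genes
  tg$de <- as.integer(tg$de)
  tg$tested <- as.integer(tg$tested)
  tg$selected <- as.integer(tg$selected)
  write_tsv_lf(tg, p("truth_genes.tsv"))
  write_study_config(study$config, p("config.yaml"))
  invisible(dir)
}

#' Consistently rename gene ids across all tables of a study
#'
#' Replaces every gene id with an opaque identifier (consistent across
#' the orthogroup, DE, selection and GO tables). Used to verify that the
#' pipeline does not exploit the structure the generator encodes in its
#' readable ids.
#'
#' @param study a `synthetic_study`.
#' @param seed seed for the permutation of replacement ids.
#' @return The study with scrambled gene ids (truth tables included).
#' @export
scramble_gene_ids <- function(study, seed = 0) {
  set.seed(as.integer(seed))
  old <- study$orthogroups$genes$gene_id
  new <- sprintf("g%08d", sample(length(old)))
  map <- stats::setNames(new, old)
  relabel <- function(x) unname(map[x])
  study$orthogroups$genes$gene_id <- relabel(study$orthogroups$genes$gene_id)
  for (s in names(study$de_tables))
    study$de_tables[[s]]$gene_id <- relabel(study$de_tables[[s]]$gene_id)
  study$selection$gene_id <- relabel(study$selection$gene_id)
  study$go_map$gene_id <- relabel(study$go_map$gene_id)
  study$truth$genes$gene_id <- relabel(study$truth$genes$gene_id)
  study
}

#' Score a pipeline run against the generator's truth record
#'
#' Computes precision and recall of the expansion calls per hypothesis
#' (planted families restricted to the Conserved Set), compares observed
#' per-species DE rates with the configured rates, and reports tier
#' counts.
#'
#' @param study the `synthetic_study` that produced the inputs.
#' @param run a `study_run` from [run_study()] on those inputs.
#' @return List with `expansion` (data.frame per hypothesis: planted,
#'   called, recall, precision), `de_rates` (data.frame per species:
#'   configured, observed) and `tiers`.
#' @export
recover_truth <- function(study, run) {
  th <- study$truth$hogs
  exp_mat <- run$expansion
  if (length(setdiff(rownames(exp_mat), th$hog_id)))
    stop("run and truth do not share family ids (mismatched seeds?)")
  rows <- lapply(colnames(exp_mat), function(hid) {
    planted <- th$hog_id[th$pattern == hid & th$conserved]
    called <- rownames(exp_mat)[exp_mat[, hid]]
    data.frame(hypothesis = hid, planted = length(planted),
               called = length(called),
               recall = if (length(planted))
                 mean(planted %in% called) else NA_real_,
               precision = if (length(called))
                 mean(called %in% planted) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tg <- study$truth$genes
  de_rates <- data.frame(
    species = names(study$sim$de_base_rate),
    configured = unname(study$sim$de_base_rate),
    observed = vapply(names(study$sim$de_base_rate), function(s)
      mean(tg$de[tg$species == s]), 0),
    stringsAsFactors = FALSE)
  list(expansion = do.call(rbind, rows), de_rates = de_rates,
       tiers = run$tiers$counts)
}
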