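# construct a study where every tier flag is decided by hand:
# counts give both-tolerant expansions, DE placement gives the tiers
tier_fixture <- function(n = 20, expanded = 1:9,
                         de_tolA = 1:9, de_tolB = c(1:4, 10),
                         de_sen = c(3, 4, 11), down_tolB = integer()) {
  cfg <- make_config()
  hogs <- sprintf("H%02d", seq_len(n))
  counts <- matrix(1L, n, 4, dimnames = list(hogs, cfg$species$name))
  counts[expanded, c("tolA", "tolB")] <- 4L
  cs <- filter_conserved(og_from_counts(counts))
  de_for <- function(sp, de_rows, down_rows = integer()) {
    g <- cs$genes[cs$genes$species == sp, ]
    in_de <- g$hog_id %in% hogs[de_rows]
    flag_degs(de_tab(g$gene_id,
                     ifelse(g$hog_id %in% hogs[down_rows], -1, 1),
                     ifelse(in_de, 0.01, 0.9), sp))
  }
  de_list <- list(tolA = de_for("tolA", de_tolA),
                  tolB = de_for("tolB", de_tolB, down_tolB),
                  senA = de_for("senA", de_sen),
                  senB = de_for("senB", integer()))
  de_flags <- hog_de_flags(cs, de_list)
  list(cfg = cfg, cs = cs, de_flags = de_flags, hogs = hogs,
       em = expansion_matrix(cs, cfg))
}

test_that("tier flags implement the nested candidate definitions", {
  # expanded 1:9; DE tolA 1:9, DE tolB 1:4, DE sensitive in 3,4
  fx <- tier_fixture()
  rec <- build_tiers(fx$cs, fx$em, fx$de_flags, fx$cfg, "tolerant")
  expect_equal(sum(rec$candidate), 9)      # expanded & DE in >= 1 tolerant
  expect_equal(sum(rec$conserved_de), 4)   # ... & DE in both tolerant
  expect_equal(sum(rec$unique_up), 2)      # ... & no sensitive DE, all up
  expect_true(all(rec$hog_id[rec$unique_up] %in% c("H01", "H02")))
  # nesting holds row-wise
  expect_true(all(rec$conserved_de[rec$unique_up]))
  expect_true(all(rec$candidate[rec$conserved_de]))
})

test_that("a down-regulated tolerant DEG blocks unique_up", {
  fx <- tier_fixture(down_tolB = 1)
  rec <- build_tiers(fx$cs, fx$em, fx$de_flags, fx$cfg, "tolerant")
  expect_false(rec$unique_up[rec$hog_id == "H01"])
  expect_true(rec$conserved_de[rec$hog_id == "H01"])
})

test_that("candidate count equals independent set algebra on the matrices", {
  set.seed(31)
  sim <- synthetic_config(n_hogs = 800)
  st <- generate_study(sim, seed = 5)
  run <- run_study(st$orthogroups, st$de_tables, st$config)
  rec <- run$tiers$tolerant$records
  expanded <- run$expansion[, "both_tolerant"]
  de_any_tol <- rowSums(
    run$de_flags$any_deg[, c("tolA", "tolB"), drop = FALSE]) >= 1
  expect_equal(sum(rec$candidate), sum(expanded & de_any_tol))
  expect_true(all(rec$unique_up <= rec$conserved_de))
  expect_true(all(rec$conserved_de <= rec$candidate))
})

test_that("contrast tiers are the phenotype-swapped image of candidates", {
  sim <- synthetic_config(n_hogs = 600)
  st <- generate_study(sim, seed = 9)
  run <- run_study(st$orthogroups, st$de_tables, st$config)
  swapped_cfg <- study_config(
    species = st$config$species$name,
    ploidy = st$config$species$ploidy,
    phenotype = ifelse(st$config$species$phenotype == "tolerant",
                       "sensitive", "tolerant"),
    alpha_de = st$config$alpha_de)
  run2 <- run_study(st$orthogroups, st$de_tables, swapped_cfg)
  for (flag in c("candidate", "conserved_de", "unique_up"))
    expect_equal(run2$tiers$tolerant$records[[flag]],
                 run$tiers$sensitive$records[[flag]])
})

test_that("conserved-DE and unique-DE enrichments use the stated universes", {
  fx <- tier_fixture()
  rec <- build_tiers(fx$cs, fx$em, fx$de_flags, fx$cfg, "tolerant")
  r <- conserved_de_enrichment(rec, fx$de_flags, fx$cfg)
  # universe: DE in >= 1 tolerant = 1:10 (tolB adds H10), property: both = 1:4
  expect_equal(unname(r$contingency), c(4, 9, 4, 10))
  expect_match(r$universe_definition, "tolerant")
  u <- unique_de_enrichment(rec, fx$de_flags, fx$cfg)
  # universe: DE both tolerant = 1:4; property: no sensitive DE = H01,H02
  expect_equal(unname(u$contingency), c(2, 4, 2, 4))
  # partition: families with and without sensitive DE split the tier
  expect_equal(u$contingency[["k"]] +
                 sum(rec$conserved_de & (fx$de_flags$any_deg[rec$hog_id, "senA"] |
                                           fx$de_flags$any_deg[rec$hog_id, "senB"])),
               u$contingency[["n"]])
})

test_that("regulation enrichment matches the enumeration oracle", {
  # universe of 300 families, categories 100/100/100; subset 30 = 20/5/5
  cats <- rep(c("up", "down", "down_and_up"), each = 100)
  hogs <- sprintf("H%03d", 1:300)
  regulation <- factor(setNames(cats, hogs),
                       levels = c("up", "down", "down_and_up",
                                  "not_applicable"))
  subset <- c(hogs[1:20], hogs[101:105], hogs[201:205])
  out <- regulation_enrichment(subset, hogs, regulation)
  up <- out[out$category == "up", ]
  expect_equal(up$k, 20)
  expect_equal(up$p_value, oracle_tail(20, 30, 100, 300), tolerance = 1e-12)
  # universe = subset: every category has p = 1
  ident <- regulation_enrichment(hogs, hogs, regulation)
  expect_true(all(ident$p_value == 1))
})

test_that("uniform subsets stay null for every regulation category", {
  set.seed(41)
  n_sig <- 0L; n_tests <- 0L
  cats <- rep(c("up", "down", "down_and_up"), each = 80)
  hogs <- sprintf("H%03d", seq_along(cats))
  regulation <- factor(setNames(cats, hogs),
                       levels = c("up", "down", "down_and_up",
                                  "not_applicable"))
  for (i in 1:100) {
    subset <- sample(hogs, 30)
    out <- regulation_enrichment(subset, hogs, regulation)
    n_sig <- n_sig + sum(out$p_value < 0.05)
    n_tests <- n_tests + nrow(out)
  }
  expect_lte(n_sig / n_tests, 0.10)
})
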