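test_that("generation is deterministic: same seed, identical bytes", {
  sim <- synthetic_config(n_hogs = 200)
  d1 <- file.path(tempdir(), "synth1"); d2 <- file.path(tempdir(), "synth2")
  generate_study(sim, seed = 7, dir = d1)
  generate_study(sim, seed = 7, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "synth3")
  generate_study(sim, seed = 8, dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d3, "orthogroups.tsv"))),
                         unname(tools::md5sum(f1[basename(f1) ==
                                                   "orthogroups.tsv"]))))
})

test_that("written tables re-read into the generated study", {
  sim <- synthetic_config(n_hogs = 150)
  d <- file.path(tempdir(), "synth_rt")
  st <- generate_study(sim, seed = 3, dir = d)
  og <- read_orthogroups(file.path(d, "orthogroups.tsv"), st$config)
  expect_equal(gene_counts(og), gene_counts(st$orthogroups))
  de <- read_de_table(file.path(d, "de_tolA.tsv"), "tolA")
  expect_equal(de$gene_id, st$de_tables$tolA$gene_id)
  expect_equal(de$padj, st$de_tables$tolA$padj, tolerance = 1e-12)
  sel <- read_selection_table(file.path(d, "selection.tsv"))
  expect_equal(sum(sel$tested), sum(st$selection$tested))
  cfg <- read_study_config(file.path(d, "config.yaml"))
  expect_equal(cfg$species, st$config$species)
})

test_that("conserved-set size matches the truth record", {
  st <- generate_study(synthetic_config(n_hogs = 500), seed = 2)
  cs <- filter_conserved(st$orthogroups)
  expect_equal(nrow(cs$hogs), sum(st$truth$hogs$conserved))
  expect_setequal(cs$hogs$hog_id,
                  st$truth$hogs$hog_id[st$truth$hogs$conserved])
})

test_that("planted expansions are always recovered (recall 1)", {
  sim <- synthetic_config(n_hogs = 1000)
  st <- generate_study(sim, seed = 11)
  run <- run_study(st$orthogroups, st$de_tables, st$config)
  rec <- recover_truth(st, run)
  expect_true(all(rec$expansion$recall[rec$expansion$planted > 0] == 1))
})

test_that("marginal DE rates are honored at null settings", {
  sim <- synthetic_config(n_hogs = 2000, conservation_coupling = 1,
                          expansion_de_multiplier = 1)
  st <- generate_study(sim, seed = 13)
  tg <- st$truth$genes
  for (s in st$config$species$name) {
    obs <- mean(tg$de[tg$species == s])
    p <- sim$de_base_rate[[s]]
    se <- sqrt(p * (1 - p) / sum(tg$species == s))
    expect_lt(abs(obs - p), 3 * se)
  }
})

test_that("calibration also preserves marginals under strong coupling", {
  sim <- synthetic_config(n_hogs = 2000, conservation_coupling = 6,
                          expansion_de_multiplier = 1)
  st <- generate_study(sim, seed = 17)
  tg <- st$truth$genes
  for (s in st$config$species$name) {
    p <- sim$de_base_rate[[s]]
    n <- sum(tg$species == s)
    # coupling inflates the variance of the mean; allow 5 binomial SE
    expect_lt(abs(mean(tg$de[tg$species == s]) - p),
              5 * sqrt(p * (1 - p) / n))
  }
})

test_that("zero DE rates leave every tier empty", {
  sim <- synthetic_config(n_hogs = 300,
                          de_base_rate = c(tolA = 0, tolB = 0,
                                           senA = 0, senB = 0))
  st <- generate_study(sim, seed = 19)
  run <- run_study(st$orthogroups, st$de_tables, st$config)
  expect_equal(unname(run$tiers$tolerant$counts["candidate"]), 0L)
  expect_equal(unname(run$tiers$sensitive$counts["candidate"]), 0L)
  expect_equal(run$conservation$observed_all, 0L)
})

test_that("the pipeline is blind to the structure of generated gene ids", {
  sim <- synthetic_config(n_hogs = 400)
  st <- generate_study(sim, seed = 23)
  run1 <- run_study(st$orthogroups, st$de_tables, st$config,
                    selection = st$selection)
  st2 <- scramble_gene_ids(st, seed = 1)
  run2 <- run_study(st2$orthogroups, st2$de_tables, st2$config,
                    selection = st2$selection)
  expect_equal(run2$battery$p_value, run1$battery$p_value)
  expect_equal(run2$tiers$tolerant$counts, run1$tiers$tolerant$counts)
  expect_equal(run2$selection$summary$n_selected,
               run1$selection$summary$n_selected)
})

test_that("infeasible planting configurations are rejected", {
  expect_error(synthetic_config(expansion_rates = c(tolA = 0.6, tolB = 0.5)),
               "infeasible planting")
  expect_error(synthetic_config(conservation_coupling = 0.5),
               "multipliers")
})

test_that("strong conservation coupling drives observed_all above expected", {
  hits <- 0L
  for (seed in 1:100) {
    st <- generate_study(synthetic_config(n_hogs = 400,
                                          conservation_coupling = 4),
                         seed = 3000 + seed)
    cs <- filter_conserved(st$orthogroups)
    de_list <- lapply(st$de_tables, flag_degs, alpha_de = 0.1)
    stats <- conservation_stats(hog_de_flags(cs, de_list))
    hits <- hits + (stats$observed_all > stats$expected_all)
  }
  expect_gte(hits, 95)
})

test_that("truth-vs-run scoring refuses mismatched studies", {
  st_a <- generate_study(synthetic_config(n_hogs = 50), seed = 1)
  st_b <- generate_study(synthetic_config(n_hogs = 80), seed = 2)
  run_b <- run_study(st_b$orthogroups, st_b$de_tables, st_b$config)
  expect_error(recover_truth(st_a, run_b), "mismatched")
})
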