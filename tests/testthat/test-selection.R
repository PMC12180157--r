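sel_tab <- function(gene_id, p, tested = !is.na(p)) {
  structure(data.frame(gene_id = gene_id, p_corrected = p, tested = tested,
                       stringsAsFactors = FALSE),
            class = c("selection_table", "data.frame"))
}

test_that("selection flagging is inclusive and skips untested genes", {
  st <- sel_tab(c("g1", "g2", "g3"), c(0.05, NA, 0.051))
  fl <- flag_selection(st, 0.05)
  expect_equal(fl$selected, c(TRUE, FALSE, FALSE))
  # 20 genes, 15 tested, 3 at p <= 0.05
  p <- c(rep(0.01, 3), rep(0.5, 12), rep(NA, 5))
  fl2 <- flag_selection(sel_tab(sprintf("g%02d", 1:20), p), 0.05)
  expect_equal(sum(fl2$tested), 15L)
  expect_equal(sum(fl2$selected), 3L)
})

test_that("raising alpha_sel never deselects a gene", {
  set.seed(23)
  p <- runif(50)
  st <- sel_tab(sprintf("g%02d", 1:50), p)
  n_sel <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.9),
                  function(a) sum(flag_selection(st, a)$selected), 0)
  expect_true(all(diff(n_sel) >= 0))
})

test_that("gene-level enrichment restricts both sides to tested genes", {
  # universe: 40 DEGs, 8 selected; subset: 10 of them, 5 selected
  genes <- sprintf("g%02d", 1:45)
  p <- c(rep(0.01, 5), rep(0.5, 5),          # subset: 5 selected, 5 not
         rep(0.01, 3), rep(0.5, 27),         # rest of universe: 3 selected
         rep(NA, 5))                          # untested, must drop out
  fl <- flag_selection(sel_tab(genes, p), 0.05)
  r <- selection_enrichment_genes(genes[1:10], genes, fl, "over")
  expect_equal(unname(r$contingency), c(5, 10, 8, 40))
  expect_equal(r$p_value, hypergeom_over(5, 10, 8, 40))
  expect_error(selection_enrichment_genes(genes[1:2], genes[41:45], fl),
               "no tested genes")
})

# a small study where every selection/DE flag is planted by hand
family_fixture <- function() {
  cfg <- make_config()
  counts <- matrix(1L, 10, 4, dimnames = list(sprintf("H%02d", 1:10),
                                              cfg$species$name))
  counts[, "tolA"] <- 2L
  cs <- filter_conserved(og_from_counts(counts))
  ga <- cs$genes[cs$genes$species == "tolA", ]
  # every tolA gene is a DEG
  de_list <- list(tolA = flag_degs(de_tab(ga$gene_id, 1, 0.01, "tolA")))
  list(cfg = cfg, cs = cs, ga = ga, de_list = de_list)
}

test_that("family-level enrichment uses the >=1-selected-DEG rule", {
  fx <- family_fixture()
  # plant successes in H01-H03 (one selected DEG each); H10's DEGs untested
  p <- rep(0.5, nrow(fx$ga))
  first_of <- match(sprintf("H%02d", 1:10), fx$ga$hog_id)
  p[first_of[1:3]] <- 0.01
  untested <- fx$ga$hog_id == "H10"
  p[untested] <- NA
  fl <- flag_selection(sel_tab(fx$ga$gene_id, p), 0.05)
  de_flags <- hog_de_flags(fx$cs, fx$de_list)
  r <- selection_enrichment_families(
    sprintf("H%02d", 1:10), "tolA", fl, de_flags, fx$cs, fx$de_list,
    universe = sprintf("H%02d", 1:10), convention = "family")
  expect_equal(unname(r$contingency["k"]), 3)   # planted successes
  expect_equal(unname(r$contingency["n"]), 9)   # H10 all-untested drops out
  expect_equal(r$n_untested_hogs, 1)
})

test_that("gene- and family-level counts agree with one DEG per family", {
  fx <- family_fixture()
  # keep only one DEG per family
  one <- fx$ga[!duplicated(fx$ga$hog_id), ]
  de_list <- list(tolA = flag_degs(de_tab(one$gene_id, 1, 0.01, "tolA")))
  p <- rep(0.5, nrow(one)); p[1:4] <- 0.01
  fl <- flag_selection(sel_tab(one$gene_id, p), 0.05)
  de_flags <- hog_de_flags(fx$cs, de_list)
  fam <- selection_enrichment_families(one$hog_id, "tolA", fl, de_flags,
                                       fx$cs, de_list, universe = one$hog_id,
                                       convention = "family")
  gene <- selection_enrichment_genes(one$gene_id, one$gene_id, fl, "over")
  expect_equal(fam$contingency, gene$contingency)
})

test_that("independent planting keeps both report designs near the null", {
  n_sig <- c(a = 0L, b = 0L)
  for (seed in 1:100) {
    sim <- synthetic_config(n_hogs = 300, conservation_coupling = 1,
                            expansion_de_multiplier = 1,
                            selection_de_multiplier = 1)
    st <- generate_study(sim, seed = 1000 + seed)
    cs <- filter_conserved(st$orthogroups)
    em <- expansion_matrix(cs, st$config)
    de_list <- lapply(st$de_tables, flag_degs, alpha_de = 0.1)
    fl <- flag_selection(st$selection, 0.05)
    tabs <- selection_report_tables(cs, em, de_list, fl, st$config)
    n_sig["a"] <- n_sig["a"] + (tabs$degs_vs_all$p_value[1] < 0.05)
    n_sig["b"] <- n_sig["b"] + (tabs$expanded_vs_all$p_value[1] < 0.05)
  }
  expect_lte(n_sig[["a"]], 10)
  expect_lte(n_sig[["b"]], 10)
})
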