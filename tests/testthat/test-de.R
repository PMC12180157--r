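test_that("DE flagging is inclusive at the cutoff and sign-aware", {
  tab <- de_tab(c("g1", "g2", "g3", "g4"),
                log2fc = c(1.3, -0.5, 0.8, 2.0),
                padj = c(0.04, 0.10, NA, 0.2))
  fl <- flag_degs(tab, alpha_de = 0.1)
  expect_equal(fl$de, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fl$direction, c("up", "down", NA, NA))
  degen <- de_tab("g1", log2fc = 0, padj = 0.01)
  expect_error(flag_degs(degen), "log2fc = 0")
})

test_that("family DE counts separate DEG tallies from family tallies", {
  counts <- matrix(2L, 10, 2, dimnames = list(sprintf("H%02d", 1:10),
                                              c("A", "B")))
  cs <- filter_conserved(og_from_counts(counts))
  genes_a <- cs$genes$gene_id[cs$genes$species == "A"]
  # 6 DEGs of species A in 4 families: H01 holds 3 (2 members + not possible),
  # so place 2 in H01, 2 in H02, 1 in H03, 1 in H04
  de_genes <- c(genes_a[cs$genes$hog_id[cs$genes$species == "A"] %in%
                          c("H01", "H02")],
                genes_a[match(c("H03", "H04"),
                              cs$genes$hog_id[cs$genes$species == "A"])])
  tab <- de_tab(genes_a, log2fc = 1, padj = ifelse(genes_a %in% de_genes,
                                                  0.01, 0.5), species = "A")
  fl <- hog_de_flags(cs, list(A = flag_degs(tab)))
  s <- fl$summary[fl$summary$species == "A", ]
  expect_equal(s$n_deg_in_set, 6L)
  expect_equal(s$n_hogs_with_deg, 4L)
  # one family, several DEGs: counted once as family, twice as DEGs
  expect_equal(unname(fl$n_up["H01", "A"]), 2L)
  expect_equal(sum(fl$any_deg[, "A"]), 4L)
})

test_that("unmapped DE genes are tallied, never silently dropped", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("H1", "H2"), c("A", "B")))
  cs <- filter_conserved(og_from_counts(counts))
  tab <- de_tab(c(cs$genes$gene_id[1], "orphan"), log2fc = 1,
                padj = c(0.01, 0.01), species = "A")
  fl <- hog_de_flags(cs, list(A = flag_degs(tab)))
  s <- fl$summary[fl$summary$species == "A", ]
  expect_equal(s$n_deg, 2L)
  expect_equal(s$n_deg_in_set, 1L)
  expect_equal(s$n_unassigned, 1L)
})

test_that("regulation categories need two DEGs and track direction", {
  n_up <- matrix(c(2L, 1L, 1L, 0L, 0L), 5, 1,
                 dimnames = list(paste0("H", 1:5), "A"))
  n_down <- matrix(c(0L, 1L, 0L, 2L, 0L), 5, 1,
                   dimnames = list(paste0("H", 1:5), "A"))
  fl <- structure(list(n_up = n_up, n_down = n_down,
                       any_deg = (n_up + n_down) >= 1),
                  class = "hog_de_flags")
  cat <- regulation_category(fl)
  expect_equal(as.character(cat),
               c("up", "down_and_up", "not_applicable", "down",
                 "not_applicable"))
  # partition: categorized families = families with >= 2 DEGs
  expect_equal(sum(cat != "not_applicable"), sum(n_up + n_down >= 2))
})

test_that("conservation null reproduces hand-computed toy statistics", {
  # two species, N = 4, each with 2 DE families, all-pattern observed 3
  st <- conservation_null(c(a = 2, b = 2), 4, observed_all = 3)
  expect_equal(st$p_s4, 0.25)
  expect_equal(st$expected_all, 1)
  expect_equal(st$chisq_all$statistic, (3 - 1)^2 / 1 + (1 - 3)^2 / 3)
  expect_equal(st$chisq_all$p_value,
               pchisq(16 / 3, df = 1, lower.tail = FALSE))
})

test_that("conservation null is label-invariant and handles degeneracy", {
  s <- c(10, 20, 30)
  st1 <- conservation_null(s, 40)
  st2 <- conservation_null(rev(s), 40)
  expect_equal(st1$p_s4, st2$p_s4)
  expect_equal(st1$p_f4, st2$p_f4)
  expect_lte(st1$p_s4, min(st1$p_s))
  expect_lte(st1$expected_all + st1$expected_none, 40)
  # all species DE everywhere: expected_all = N
  deg <- conservation_null(c(5, 5), 5)
  expect_equal(deg$p_s4, 1)
  expect_equal(deg$expected_all, 5)
  expect_error(conservation_null(c(1, 2), 0), "empty")
})

test_that("conservation stats derive observed counts from the flag matrix", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE, FALSE), 4, 2,
              dimnames = list(paste0("H", 1:4), c("A", "B")))
  fl <- list(any_deg = m)
  st <- conservation_stats(fl)
  expect_equal(st$observed_all, 1L)  # H1 only
  expect_equal(st$observed_none, 1L) # H4 only
  expect_equal(st$p_s, c(A = 0.5, B = 0.5))
})
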