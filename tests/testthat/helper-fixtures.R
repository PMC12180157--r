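# shared fixtures: a four-species panel mirroring the synthetic defaults
make_config <- function(...) {
  study_config(
    species   = c("tolA", "tolB", "senA", "senB"),
    ploidy    = c(2, 2, 2, 4),
    phenotype = c("tolerant", "tolerant", "sensitive", "sensitive"),
    ...
  )
}

# build an orthogroup_table directly from a copy-count matrix
og_from_counts <- function(counts, species = colnames(counts)) {
  hog_ids <- rownames(counts)
  if (is.null(hog_ids)) hog_ids <- sprintf("H%03d", seq_len(nrow(counts)))
  rows <- lapply(seq_along(species), function(j) {
    reps <- counts[, j]
    data.frame(hog_id = rep(hog_ids, reps),
               species = rep(species[j], sum(reps)),
               gene_id = sprintf("%s.%s.%d", rep(species[j], sum(reps)),
                                 rep(hog_ids, reps), sequence(reps)),
               stringsAsFactors = FALSE)
  })
  expanDE:::new_orthogroup_table(
    do.call(rbind, rows),
    data.frame(hog_id = hog_ids, og_id = NA_character_,
               stringsAsFactors = FALSE),
    species)
}

# a de_table from explicit vectors
de_tab <- function(gene_id, log2fc, padj, species = "sp") {
  structure(data.frame(gene_id = gene_id, log2fc = log2fc, padj = padj,
                       base_mean = NA_real_, stringsAsFactors = FALSE),
            species = species, class = c("de_table", "data.frame"))
}

# independent hypergeometric tail oracle: plain choose() summation,
# no shared code with the package's log-space implementation
oracle_tail <- function(k, n, K, N, upper = TRUE) {
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  xs <- if (upper) k:hi else lo:k
  xs <- xs[xs >= lo & xs <= hi]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
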