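#' Union GO annotation of families
#'
#' Annotates each family with the union of the GO terms of all its member
#' genes from every species, so the annotations of all species are
#' considered. Genes without annotation contribute nothing; a family may
#' end up with an empty term set. The operation is idempotent and
#' order-independent.
#'
#' @param conserved a `conserved_set`.
#' @param go_map long data.frame `gene_id`, `species`, `term` from
#'   [read_go_map()] (a wide form with a comma-separated `go_terms`
#'   column is accepted and expanded).
#' @return Named list, one character vector of terms per hog id.
#' @export
union_annotate <- function(conserved, go_map) {
  if (is.null(go_map$term) && !is.null(go_map$go_terms)) {
    toks <- strsplit(go_map$go_terms, ",[ ]?")
    toks <- lapply(toks, function(x) x[nzchar(x)])
    go_map <- data.frame(gene_id = rep(go_map$gene_id, lengths(toks)),
                         species = rep(go_map$species, lengths(toks)),
                         term = unlist(toks, use.names = FALSE),
                         stringsAsFactors = FALSE)
  }
  genes <- conserved$genes
  key_g <- paste(genes$species, genes$gene_id, sep = "\r")
  key_m <- paste(go_map$species, go_map$gene_id, sep = "\r")
  idx <- match(key_m, key_g)
  hit <- !is.na(idx)
  ann <- lapply(
    split(go_map$term[hit], factor(genes$hog_id[idx[hit]],
                                   levels = conserved$hogs$hog_id)),
    function(x) sort(unique(x)))
  ann
}

#' GO over-representation of a family subset
#'
#' Classic term-by-term one-sided Fisher (hypergeometric upper-tail) test
#' of every term present in the subset against the background, on the
#' flat family-level annotations (no DAG propagation or term
#' decorrelation). A term is `reported` when `p < 0.05` (strict) and it
#' annotates at least two subset families.
#'
#' @param subset_hogs character vector of family ids; must be contained
#'   in `background_hogs`.
#' @param background_hogs character vector of family ids (normally the
#'   whole Conserved Set).
#' @param annotation named term list from [union_annotate()].
#' @return Data.frame sorted by `p_value`: `term`, `k`, `n`, `K`, `N`,
#'   `fold`, `p_value`, `reported`.
#' @export
go_over_representation <- function(subset_hogs, background_hogs, annotation) {
  if (length(setdiff(subset_hogs, background_hogs)))
    stop("subset is not contained in the background")
  ann <- annotation[intersect(names(annotation), background_hogs)]
  long <- data.frame(hog_id = rep(names(ann), lengths(ann)),
                     term = unlist(ann, use.names = FALSE),
                     stringsAsFactors = FALSE)
  in_sub <- long$hog_id %in% subset_hogs
  terms <- sort(unique(long$term[in_sub]))
  N <- length(background_hogs)
  n <- length(unique(subset_hogs))
  K_all <- table(factor(long$term, levels = terms))
  k_all <- table(factor(long$term[in_sub], levels = terms))
  rows <- lapply(seq_along(terms), function(i) {
    k <- as.integer(k_all[i]); K <- as.integer(K_all[i])
    p <- hypergeom_over(k, n, K, N)
    data.frame(term = terms[i], k = k, n = n, K = K, N = N,
               fold = (k / n) / (K / N), p_value = p,
               reported = p < 0.05 & k >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p_value = numeric(), reported = logical()))
  out[order(out$p_value, out$term), , drop = FALSE]
}
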