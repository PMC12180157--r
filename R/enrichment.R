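#' One-sided hypergeometric tail probabilities
#'
#' Exact tail probabilities for drawing `k` marked items in a sample of
#' `n` from a population of `N` containing `K` marked items. The upper
#' tail `P(X >= k)` tests over-representation, the lower tail `P(X <= k)`
#' under-representation. Tails are computed by exact summation of
#' log-density terms (no normal approximation); p-values are returned at
#' full precision.
#'
#' @param k observed successes in the sample.
#' @param n sample size.
#' @param K population successes.
#' @param N population size.
#' @return The tail probability in `[0, 1]`.
#' @examples
#' hypergeom_over(3, 5, 4, 10)  # 66/252
#' @export
hypergeom_over <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  hi <- min(n, K)
  if (k > hi) return(0)
  support <- max(0, n - (N - K)):hi
  logsum_dhyper(support[support >= k], K, N, n)
}

#' @rdname hypergeom_over
#' @export
hypergeom_under <- function(k, n, K, N) {
  check_contingency(k, n, K, N)
  lo <- max(0, n - (N - K))
  if (k < lo) return(0)
  support <- lo:min(n, K)
  logsum_dhyper(support[support <= k], K, N, n)
}

logsum_dhyper <- function(xs, K, N, n) {
  lp <- stats::dhyper(xs, K, N - K, n, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

check_contingency <- function(k, n, K, N) {
  v <- c(k = k, n = n, K = K, N = N)
  if (any(v < 0) || any(v != floor(v)))
    stop("contingency counts must be nonnegative integers")
  if (n > N || K > N) stop("sample/successes exceed population")
  if (k > min(n, K)) stop("k exceeds min(n, K)")
  if (n - k > N - K) stop("sample failures exceed population failures")
  invisible(v)
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' For the table `(a, b; c, d)` the one-sided exact p equals the
#' hypergeometric tail with population `N = a+b+c+d`, population successes
#' `K = a+b`, sample size `n = a+c` and sample successes `k = a`. The
#' all-zero table returns `p = 1` by convention.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param direction `"over"` (upper tail) or `"under"` (lower tail).
#' @return The one-sided p-value.
#' @export
fisher_one_sided <- function(a, b, c, d, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (a + b + c + d == 0) return(1)
  if (direction == "over") hypergeom_over(a, a + c, a + b, a + b + c + d)
  else hypergeom_under(a, a + c, a + b, a + b + c + d)
}

#' Enrichment of a property in a subset of a universe
#'
#' Builds the contingency (`N` = universe size, `K` = universe items with
#' the property, `n` = subset size, `k` = subset items with the property)
#' and applies the requested one-sided hypergeometric tail. The 0.05
#' convention used in reporting never filters results here.
#'
#' @param subset character vector of item ids; must be contained in
#'   `universe`.
#' @param property character vector of item ids carrying the property
#'   (intersected with the universe).
#' @param universe character vector of all item ids.
#' @param direction `"over"` or `"under"`.
#' @return An `enrichment_result`: list with `contingency` (named `k`,
#'   `n`, `K`, `N`), `direction`, `p_value` and `fold`
#'   (`(k/n) / (K/N)`).
#' @export
enrich <- function(subset, property, universe, direction = c("over", "under")) {
  direction <- match.arg(direction)
  universe <- unique(universe)
  subset <- unique(subset)
  if (length(setdiff(subset, universe)))
    stop("subset is not contained in the universe (e.g. '",
         setdiff(subset, universe)[1], "')")
  property <- intersect(unique(property), universe)
  enrich_counts(length(intersect(subset, property)), length(subset),
                length(property), length(universe), direction)
}

#' @rdname enrich
#' @param k,n,K,N contingency counts (subset successes, subset size,
#'   universe successes, universe size) for when the sets themselves are
#'   not at hand.
#' @export
enrich_counts <- function(k, n, K, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  p <- if (direction == "over") hypergeom_over(k, n, K, N)
       else hypergeom_under(k, n, K, N)
  structure(list(
    contingency = c(k = k, n = n, K = K, N = N),
    direction = direction, p_value = p,
    fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  ct <- x$contingency
  cat(sprintf("%s-representation: %d/%d vs %d/%d, fold = %.2f, p = %.2g\n",
              x$direction, ct["k"], ct["n"], ct["K"], ct["N"], x$fold,
              x$p_value))
  invisible(x)
}

#' Run a battery of enrichment tests from a manifest
#'
#' Each manifest row names a subset, a property and a universe (keys into
#' `sets`) plus a direction; one result row is emitted per test. P-values
#' are reported raw (matching the reporting convention of the analysis);
#' an optional Benjamini-Hochberg column can be added.
#'
#' @param manifest data.frame with columns `test_id`, `universe`,
#'   `subset`, `property`, `direction`.
#' @param sets named list of character vectors of item ids.
#' @param bh add a `p_bh` Benjamini-Hochberg column (default `FALSE`).
#' @return Data.frame with one row per test: ids, contingency counts,
#'   `fold`, `direction` and `p_value`.
#' @export
enrichment_battery <- function(manifest, sets, bh = FALSE) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    r <- enrich(sets[[m$subset]], sets[[m$property]], sets[[m$universe]],
                m$direction)
    data.frame(test_id = m$test_id, universe = m$universe, subset = m$subset,
               property = m$property, direction = m$direction,
               k = r$contingency["k"], n = r$contingency["n"],
               K = r$contingency["K"], N = r$contingency["N"],
               fold = r$fold, p_value = r$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
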