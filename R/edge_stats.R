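#' Hypergeometric parameter quadruple
#'
#' The (N, n, K, k) parameters of the edge-significance test: `N` genes (or
#' regulations) in the population, `n` drawn (genes in GS1, or
#' out-regulations of GS1's unique genes), `K` marked (genes in GS2, or
#' in-regulations of GS2's unique genes), `k` observed marked draws (shared
#' genes, or GS1-to-GS2 regulations).
#'
#' @param N,n,K,k Nonnegative integers with `n <= N`, `K <= N`,
#'   `max(0, n + K - N) <= k <= min(n, K)`.
#' @return A `hypergeom_params` list.
#' @export
hypergeom_params <- function(N, n, K, k) {
  v <- c(N = N, n = n, K = K, k = k)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    abort("N, n, K, k must be nonnegative integers")
  }
  if (n > N || K > N) abort("n and K cannot exceed N")
  if (k > min(n, K) || k < max(0, n + K - N)) {
    abort(sprintf("k = %d outside the support [%d, %d] for (N=%d, n=%d, K=%d)",
                  k, max(0, n + K - N), min(n, K), N, n, K))
  }
  structure(as.list(v), class = "hypergeom_params")
}

#' Hypergeometric edge p-value
#'
#' Significance of an observed overlap or cross-regulation count under the
#' hypergeometric model: drawing `n` items from a population of `N`
#' containing `K` marked items, how surprising are `k` or more marked
#' draws? The default `"upper-tail"` mode returns the one-sided enrichment
#' probability P(X >= k); `"point"` returns the single point mass P(X = k).
#' All arithmetic is done in log space so p-values around 1e-300 (deeply
#' overlapping pathway pairs) remain representable.
#'
#' @param params A [hypergeom_params()] (or list with fields N, n, K, k).
#' @param mode `"upper-tail"` (default) or `"point"`.
#' @param log.p Return the natural log of the probability.
#' @return A probability in \[0, 1\] (or its log).
#' @examples
#' # a 46-gene set sharing 16 genes with a 347-gene list in an
#' # 11,111-gene universe
#' hypergeom_pvalue(hypergeom_params(11111, 46, 347, 16))
#' @export
hypergeom_pvalue <- function(params, mode = c("upper-tail", "point"),
                             log.p = FALSE) {
  mode <- match.arg(mode)
  p <- do.call(hypergeom_params, params[c("N", "n", "K", "k")])
  lp <- if (mode == "point") {
    dhyper(p$k, m = p$K, n = p$N - p$K, k = p$n, log = TRUE)
  } else if (p$k == 0L) {
    0
  } else {
    phyper(p$k - 1L, m = p$K, n = p$N - p$K, k = p$n,
           lower.tail = FALSE, log.p = TRUE)
  }
  if (log.p) lp else exp(lp)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure: with the p-values sorted ascending, reject
#' all hypotheses up to the largest i with p_(i) <= (i/m) * alpha. The
#' returned q-values are `min over j >= i of m * p_(j) / j` capped at 1, so
#' `rejected` is equivalent to `q <= alpha`. Flags are returned in input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Target false discovery rate in (0, 1).
#' @return Tibble with columns `p`, `q`, `rejected`, in input order.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(tibble(p = double(), q = double(),
                                     rejected = logical()))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, rejected = q <= alpha)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` with fixed
#' margins: the sum of hypergeometric probabilities of all tables no more
#' probable than the observed one. Degenerate margins give p = 1.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return A probability in \[0, 1\].
#' @export
fisher_exact <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    abort("cell counts must be nonnegative integers")
  }
  if (sum(v) == 0L) return(1)
  m <- matrix(v, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(1)
  fisher.test(m, alternative = "two.sided")$p.value
}
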