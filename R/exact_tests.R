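#' Two-sided Fisher exact p-values for 2x2 methylation count tables
#'
#' Computes the two-sided Fisher exact test p-value for tables of the form
#' \code{[[meth_a, unmeth_a], [meth_b, unmeth_b]]}, vectorised over pairs.
#' Discordance screens run over tens of thousands of paralogous CpG pairs,
#' so the test is evaluated directly on the hypergeometric support rather
#' than through repeated calls to [stats::fisher.test()]; the two agree to
#' numerical precision (see the package tests).
#'
#' Two-sidedness follows the minimum-likelihood convention: the p-value is
#' the sum of probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. As in
#' [stats::fisher.test()], a relative tolerance guards the comparison
#' against floating-point ties.
#'
#' @param meth_a,unmeth_a Methylated/unmethylated read counts at the first
#'   copy (integer vectors).
#' @param meth_b,unmeth_b Counts at the second copy.
#' @param tol Relative tolerance used when comparing table probabilities.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_p(5, 5, 5, 5)      # identical rows -> 1
#' fisher_exact_p(10, 0, 0, 10)    # maximally discordant
#' @export
fisher_exact_p <- function(meth_a, unmeth_a, meth_b, unmeth_b, tol = 1e-7) {
  n <- length(meth_a)
  stopifnot(
    length(unmeth_a) == n, length(meth_b) == n, length(unmeth_b) == n,
    all(meth_a >= 0), all(unmeth_a >= 0), all(meth_b >= 0), all(unmeth_b >= 0)
  )
  depth_a <- meth_a + unmeth_a
  depth_b <- meth_b + unmeth_b
  if (any(depth_a == 0 | depth_b == 0)) {
    stop("zero-depth site encountered; apply depth filters before testing")
  }
  vapply(seq_len(n), function(i) {
    na <- depth_a[i]
    nb <- depth_b[i]
    k <- meth_a[i] + meth_b[i]
    lo <- max(0L, k - nb)
    hi <- min(k, na)
    d <- dhyper(lo:hi, na, nb, k)
    min(1, sum(d[d <= d[meth_a[i] - lo + 1L] * (1 + tol)]))
  }, numeric(1))
}

#' Two-sided exact binomial p-values for window read-count pairs
#'
#' Exact two-sided binomial test of \code{x} successes in \code{n} trials
#' with success probability \code{prob}, vectorised; the two-sided p-value
#' uses the same minimum-likelihood convention as [fisher_exact_p()] and
#' matches [stats::binom.test()]. Untestable windows (\code{n == 0}) return
#' \code{NA}.
#'
#' @param x Number of successes (e.g. reads on the first duplicon copy).
#' @param n Number of trials (total reads across the window pair).
#' @param prob Success probability under the null; the within-sample design
#'   compares two windows of the same library, so the default is 0.5.
#' @param tol Relative tolerance for probability ties.
#' @return Numeric vector of p-values; NA where \code{n == 0}.
#' @examples
#' binom_exact_p(7, 14)    # symmetric -> 1
#' binom_exact_p(10, 10)   # one-sided extreme: 2 * 0.5^10
#' @export
binom_exact_p <- function(x, n, prob = 0.5, tol = 1e-7) {
  stopifnot(length(n) == length(x), all(x >= 0), all(x <= n))
  vapply(seq_along(x), function(i) {
    if (n[i] == 0L) return(NA_real_)
    d <- dbinom(0:n[i], n[i], prob)
    min(1, sum(d[d <= d[x[i] + 1L] * (1 + tol)]))
  }, numeric(1))
}
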