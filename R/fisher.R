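# Two-tailed Fisher's exact test for 2x2 tables, computed in log space so
# tables with counts in the thousands do not underflow.

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Sums, over all tables sharing the observed margins, the hypergeometric
#' probabilities that do not exceed the probability of the observed table
#' (the two-sided convention of standard statistical software). The
#' comparison uses a small relative tolerance so ties at the observed
#' probability are not misclassified by floating point.
#'
#' @param a,b,c,d nonnegative integer cells: `a` = set-A elements with the
#'   feature, `b` = set-A without, `c` = set-B with, `d` = set-B without.
#'   Alternatively `a` may be a 2x2 matrix `rbind(c(a, b), c(c, d))`.
#' @param rel_tol relative tolerance on the probability comparison.
#' @return The two-tailed p-value, in (0, 1].
#' @examples
#' fisher_exact_two_tailed(3, 1, 1, 3) # 34/70
#' fisher_exact_two_tailed(152, 56, 738, 552)
#' @export
fisher_exact_two_tailed <- function(a, b = NULL, c = NULL, d = NULL, rel_tol = 1e-7) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || any(!is.finite(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("all four cells must be nonnegative integers")
  }
  a <- round(a); b <- round(b); c <- round(c); d <- round(d)
  m1 <- a + b  # size of set A
  m2 <- c + d  # size of set B
  k <- a + c   # elements with the feature
  if (m1 == 0 || m2 == 0 || k == 0 || b + d == 0) {
    stop("a zero margin leaves Fisher's exact test undefined")
  }
  x <- seq.int(max(0, k - m2), min(k, m1))
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  logp_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= logp_obs + log1p(rel_tol)])))
}
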