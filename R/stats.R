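#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are removed first (the signed-rank convention); if all
#' differences are zero the test is degenerate and `p = 1` is returned with
#' a warning. For n <= 25 the exact null distribution of the signed-rank
#' statistic is computed by dynamic programming over the (possibly tied,
#' average) ranks — equivalent to enumerating all `2^n` sign assignments;
#' above that the normal approximation with continuity and tie correction
#' applies.
#'
#' @param x,y equal-length paired samples.
#' @return two-sided p-value.
#' @export
wilcoxon_paired <- function(x, y) {
  check_that(length(x) == length(y), "x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  n <- length(d)
  if (n <= 25) {
    r2 <- as.integer(round(2 * rank(abs(d)))) # doubled ranks are integers
    w2 <- sum(r2[d > 0])
    tot <- sum(r2)
    cnt <- c(1, rep(0, tot)) # counts of subset sums, index = sum + 1
    for (ri in r2)
      cnt <- cnt + c(rep(0, ri), cnt[seq_len(tot + 1 - ri)])
    cdf_le <- sum(cnt[seq_len(w2 + 1)]) / 2^n
    cdf_ge <- sum(cnt[(w2 + 1):(tot + 1)]) / 2^n
    min(1, 2 * min(cdf_le, cdf_ge))
  } else {
    suppressWarnings(
      stats::wilcox.test(d, alternative = "two.sided", exact = FALSE,
                         correct = TRUE)$p.value)
  }
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject all hypotheses up to `k* = max{k : p_(k) <= alpha k / m}`.
#' Adjusted p-values are the usual step-up-path minima, so rejection is
#' equivalent to `p_adj <= alpha`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `p_adj` (adjusted p-values) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) return(list(p_adj = numeric(0), reject = logical(0)))
  check_that(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= alpha)
}
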