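#' Likelihood-ratio test between nested codon models
#'
#' Computes `-2 * (ell_null - ell_alt)` and compares it to a chi-square
#' distribution. Small negative statistics (the alternative fitting no better
#' than the null, as happens when the extra site class collapses onto a
#' boundary) are treated as estimates of zero: the statistic is clamped at 0
#' and the p-value is 1.
#'
#' @param ell_null Log-likelihood of the null (simpler) model.
#' @param ell_alt Log-likelihood of the alternative model.
#' @param df Degrees of freedom: the difference in parameter counts (2 for
#'   M2a versus M1a).
#' @param gene Optional gene label carried into the result.
#' @return A one-row data frame of class `lrt_result`: `gene`, `statistic`,
#'   `df`, `p`.
#' @examples
#' likelihood_ratio_test(-9941.731, -9924.029, df = 2)  # statistic 35.405
#' likelihood_ratio_test(-3625.094, -3625.303, df = 2)  # clamped to 0, p = 1
#' @export
likelihood_ratio_test <- function(ell_null, ell_alt, df = 2L, gene = NA_character_) {
  stopifnot(is.finite(ell_null), is.finite(ell_alt), df >= 1)
  stat <- max(0, -2 * (ell_null - ell_alt))
  out <- data.frame(gene = gene, statistic = stat, df = as.integer(df),
                    p = chisq_upper_tail(stat, df), stringsAsFactors = FALSE)
  class(out) <- c("lrt_result", "data.frame")
  out
}

#' Chi-square upper tail probability
#'
#' Survival function of the chi-square distribution; for `df = 2` this equals
#' `exp(-x/2)` analytically.
#'
#' @param x Observed statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
chisq_upper_tail <- function(x, df) {
  stopifnot(all(x >= 0), all(df >= 1))
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, the adjusted value at rank i is `min over j >= i of
#' (m * p_(j) / j)` capped at 1, returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
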