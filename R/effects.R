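#' Additive, dominance, and allele-substitution effects
#'
#' Decomposes three genotype least-squares means into
#' `a = (AA - BB)/2`, `d = AB - (AA + BB)/2`, and the average allele
#' substitution effect `alpha = a + (q - p) d`, where `p` is the frequency of
#' the allele whose homozygote mean is `mean_11` and `q = 1 - p`.
#'
#' @param mean_11 LS-mean of the homozygote of the first-listed allele.
#' @param mean_12 LS-mean of the heterozygote.
#' @param mean_22 LS-mean of the other homozygote.
#' @param p Frequency of the first-listed allele.
#' @param q Frequency of the other allele (default `1 - p`).
#' @return One-row tibble: `a`, `d`, `alpha`, `p`, `q`.
#' @export
decompose_effects <- function(mean_11, mean_12, mean_22, p, q = 1 - p) {
  if (abs(p + q - 1) > 1e-9) abort("allele frequencies must satisfy p + q = 1")
  if (!all(is.finite(c(mean_11, mean_12, mean_22)))) {
    abort("genotype means must be finite")
  }
  a <- (mean_11 - mean_22) / 2
  d <- mean_12 - (mean_11 + mean_22) / 2
  tibble(a = a, d = d, alpha = a + (q - p) * d, p = p, q = q)
}
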