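#' Minimal detectable standardised difference of a two-sample comparison
#'
#' The smallest difference between two group means, in units of the
#' within-group standard deviation, detectable with the given power at a
#' two-sided significance level, for equal group sizes. With 50 respondents
#' per group, 80 percent power and alpha = 0.05 this evaluates to 0.57 (2
#' decimals), the sample-size rationale used for cohort comparisons here.
#'
#' @param n_per_group Respondents per group.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return The standardised difference (Cohen's d scale).
#' @export
#' @examples
#' round(minimal_detectable_difference(50), 2)
minimal_detectable_difference <- function(n_per_group, alpha = 0.05,
                                          power = 0.8) {
  power.t.test(n = n_per_group, sig.level = alpha, power = power,
               type = "two.sample", alternative = "two.sided")$delta
}
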