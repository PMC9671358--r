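#' Analytical power for binary-outcome Mendelian randomization
#'
#' Normal-approximation power of the two-sample IVW test for a binary
#' outcome, as implemented by the standard online MR power calculators:
#' `power = Phi(sqrt(N r2 K (1-K)) |ln OR| - z_{1-alpha/2})`, where `N` is
#' the outcome sample size, `K` the case fraction and `r2` the total
#' exposure variance explained by the instruments.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Proportion of cases K in (0, 1).
#' @param r2_sum Total exposure variance explained by the instruments,
#'   in (0, 1).
#' @param or_target Odds ratio to detect.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in (0, 1). At `or_target = 1` this is `alpha/2`, the
#'   one-sided rejection probability under the null.
#' @export
#' @examples
#' mr_power_binary(100000, 0.3, 0.05, or_target = 1.090)  # ~0.80
mr_power_binary <- function(n_outcome, case_fraction, r2_sum, or_target,
                            alpha = 0.05) {
  check_power_params(n_outcome, case_fraction, r2_sum, alpha)
  stopifnot(or_target > 0)
  ncp <- sqrt(n_outcome * r2_sum * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp * abs(log(or_target)) - stats::qnorm(1 - alpha / 2))
}

#' Minimum and maximum detectable odds ratio at a target power
#'
#' Inverts the binary-outcome power approximation:
#' `or_high = exp((z_{1-alpha/2} + z_{power}) / sqrt(N r2 K (1-K)))` and
#' `or_low = 1 / or_high`, so `or_low * or_high = 1` exactly and
#' `mr_power_binary(or_high) = power_target`.
#'
#' @inheritParams mr_power_binary
#' @param power_target Target power in (0, 1) (default 0.80).
#' @return Named numeric vector `c(or_low, or_high)`.
#' @export
detectable_or <- function(n_outcome, case_fraction, r2_sum,
                          power_target = 0.80, alpha = 0.05) {
  check_power_params(n_outcome, case_fraction, r2_sum, alpha)
  stopifnot(power_target > 0, power_target < 1)
  ncp <- sqrt(n_outcome * r2_sum * case_fraction * (1 - case_fraction))
  or_high <- exp((stats::qnorm(1 - alpha / 2) + stats::qnorm(power_target)) / ncp)
  c(or_low = 1 / or_high, or_high = or_high)
}

check_power_params <- function(n_outcome, case_fraction, r2_sum, alpha) {
  if (!(n_outcome > 0)) stop("n_outcome must be positive")
  if (!(case_fraction > 0 && case_fraction < 1))
    stop("case_fraction must lie in (0, 1)")
  if (!(r2_sum > 0 && r2_sum < 1)) stop("r2_sum must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  invisible(TRUE)
}
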