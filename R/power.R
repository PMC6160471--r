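# Binary-outcome MR power calculations (normal-approximation,
# mRnd-style parameterization).

#' Power of two-sample MR with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio per SD
#' of exposure in a case-control outcome sample.  The approximate
#' standard error of the causal log-odds estimate is
#' \deqn{se = 1/\sqrt{N \, K (1-K) \, r^2}}
#' where \eqn{N} is the total outcome sample size, \eqn{K} the case
#' fraction and \eqn{r^2} the variance of the (standardized) exposure
#' explained by the instrument.  Two-sided power at level \eqn{\alpha}
#' is
#' \eqn{\Phi(|\ln OR|/se - z_{1-\alpha/2}) +
#'      \Phi(-|\ln OR|/se - z_{1-\alpha/2})}.
#'
#' @param n_outcome Total outcome sample size (cases + controls).
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2 Instrument-explained exposure variance, in (0, 1).
#' @param or_alt Alternative-hypothesis odds ratio per SD.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power in [0, 1].
#' @export
mr_power_binary <- function(n_outcome, case_fraction, r2, or_alt,
                            alpha = 0.05) {
  stopifnot(n_outcome > 0, case_fraction > 0, case_fraction < 1,
            or_alt > 0, alpha > 0, alpha < 1)
  if (r2 <= 0 || r2 >= 1)
    stop("r2 must lie strictly between 0 and 1")
  se <- 1 / sqrt(n_outcome * case_fraction * (1 - case_fraction) * r2)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or_alt)) / se
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Minimum detectable odds ratio at a target power
#'
#' Smallest odds ratio above 1 whose power reaches \code{target_power},
#' found by bisection on the log-odds scale to a tolerance of 1e-6.
#' The symmetric protective effect is the reciprocal.
#'
#' @inheritParams mr_power_binary
#' @param target_power Desired power, in (\code{alpha}, 1).
#' @return List with \code{or} (risk direction) and
#'   \code{or_protective} (its reciprocal).
#' @export
min_detectable_or <- function(n_outcome, case_fraction, r2, alpha = 0.05,
                              target_power = 0.8) {
  stopifnot(target_power > alpha, target_power < 1)
  f <- function(log_or)
    mr_power_binary(n_outcome, case_fraction, r2, exp(log_or), alpha) -
      target_power
  lo <- 0; hi <- 1e-6
  while (f(hi) < 0) hi <- hi * 2   # power is increasing in |log OR|
  while (hi - lo > 1e-6 * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  or <- exp((lo + hi) / 2)
  list(or = or, or_protective = 1 / or)
}
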