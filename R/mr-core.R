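# Causal-effect estimators on harmonized summary statistics.
#
# Notation: per variant j, (bx_j, sx_j) is the per-SD association with
# the exposure and (by_j, sy_j) the log-odds association with the
# outcome; theta is the causal log-odds per SD of exposure.

.mr_data <- function(dat, min_variants = 1L, require_positive = FALSE) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0)
    stop("harmonized data missing column(s): ", paste(miss, collapse = ", "))
  if ("exclusion_flag" %in% names(dat))
    dat <- dat[dat$exclusion_flag == "none", , drop = FALSE]
  if (nrow(dat) < min_variants)
    stop("need at least ", min_variants, " variant(s), got ", nrow(dat))
  if (any(!is.finite(dat$se_outcome)) || any(dat$se_outcome <= 0))
    stop("outcome standard errors must be positive")
  if (require_positive && any(dat$beta_exposure < 0))
    stop("exposure effects must be oriented to the increasing allele ",
         "(negative beta_exposure found); run harmonize() first")
  dat
}

.mr_estimate <- function(method, beta, se, n_variants, phi = 1,
                         intercept = NULL, intercept_se = NULL) {
  z <- stats::qnorm(0.975)
  est <- list(method = method, beta = beta, se = se,
              ci_low = beta - z * se, ci_high = beta + z * se,
              pvalue = 2 * stats::pnorm(-abs(beta / se)),
              n_variants = n_variants, phi = phi)
  if (!is.null(intercept)) {
    est$intercept <- intercept
    est$intercept_se <- intercept_se
    est$intercept_p <- 2 * stats::pnorm(-abs(intercept / intercept_se))
  }
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  cat(sprintf("%s estimate (%d variants)\n", x$method, x$n_variants))
  cat(sprintf("  log-odds per SD: %.4f (se %.4f), p = %.3g\n",
              x$beta, x$se, x$pvalue))
  cat(sprintf("  OR per SD: %.2f (95%% CI %.2f-%.2f)\n",
              or$or, or$ci_low, or$ci_high))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept: %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (x$phi > 1)
    cat(sprintf("  variance inflation phi = %.3f\n", x$phi))
  invisible(x)
}

#' Per-variant Wald (instrumental-variable) ratio estimates
#'
#' For each variant the causal effect is estimated as the ratio of the
#' outcome to the exposure association, with a first-order standard
#' error that treats the exposure effect as fixed and a second-order
#' standard error from the delta-method expansion that propagates
#' uncertainty in both numerator and denominator:
#' \deqn{se_2^2 = \sigma_Y^2/\beta_X^2 + \beta_Y^2 \sigma_X^2/\beta_X^4.}
#'
#' @param dat Harmonized instrument table (rows with a non-"none"
#'   \code{exclusion_flag} are dropped).
#' @return Data frame with columns \code{rsid}, \code{ratio},
#'   \code{se_first}, \code{se_second}.
#' @export
wald_ratio <- function(dat) {
  dat <- .mr_data(dat, 1L)
  if (any(dat$beta_exposure == 0))
    stop("non-informative instrument: beta_exposure = 0 for ",
         paste(dat$rsid[dat$beta_exposure == 0], collapse = ", "))
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  sx <- dat$se_exposure; sy <- dat$se_outcome
  data.frame(rsid = if ("rsid" %in% names(dat)) dat$rsid else seq_along(bx),
             ratio = by / bx,
             se_first = sy / abs(bx),
             se_second = sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of the per-variant ratio estimates with first-order
#' inverse-variance weights; algebraically the slope of the
#' zero-intercept regression of outcome betas on exposure betas with
#' weights \eqn{1/\sigma_Y^2}:
#' \deqn{\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2}}
#'                         {\sum_j \beta_{Xj}^2\sigma_{Yj}^{-2}}.}
#' Under the multiplicative random-effects model (the default) the
#' standard error is inflated by
#' \eqn{\phi = \max(1, \sqrt{Q/(J-1)})} where \eqn{Q} is Cochran's
#' statistic at \eqn{\hat\theta}; the fixed-effect model leaves it
#' unscaled.  A single variant degrades to the Wald ratio with a
#' warning.
#'
#' @param dat Harmonized instrument table.
#' @param effects_model \code{"multiplicative_random"} (default) or
#'   \code{"fixed"}.
#' @return An \code{mr_estimate}.
#' @export
mr_ivw <- function(dat, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  dat <- .mr_data(dat, 1L)
  J <- nrow(dat)
  if (J == 1L) {
    warning("single variant: IVW degrades to the Wald ratio")
    wr <- wald_ratio(dat)
    return(.mr_estimate("ivw", wr$ratio, wr$se_first, 1L))
  }
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  w <- 1 / dat$se_outcome^2
  sxx <- sum(w * bx^2)
  if (sxx <= 0) stop("degenerate instrument set: no exposure signal")
  beta <- sum(w * bx * by) / sxx
  se <- 1 / sqrt(sxx)
  q <- sum(w * (by - beta * bx)^2)
  phi <- 1
  if (effects_model == "multiplicative_random") {
    phi <- max(1, sqrt(q / (J - 1)))
    se <- se * phi
  }
  est <- .mr_estimate("ivw", beta, se, J, phi)
  est$cochran_q <- q
  est
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a freely
#' estimated intercept and weights \eqn{1/\sigma_Y^2}.  The slope is the
#' causal estimate; the intercept measures the average directional
#' (unbalanced) pleiotropy, and its test is the Egger intercept test.
#' Both standard errors are inflated by
#' \eqn{\phi = \max(1, \sqrt{RSS_w/(J-2)})}.  Requires at least three
#' variants and exposure effects oriented to the increasing allele.
#'
#' @param dat Harmonized instrument table.
#' @return An \code{mr_estimate} with intercept fields.
#' @export
mr_egger <- function(dat) {
  dat <- .mr_data(dat, 3L, require_positive = TRUE)
  J <- nrow(dat)
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  w <- 1 / dat$se_outcome^2
  if (stats::var(bx) == 0)
    stop("zero variance in exposure effects: Egger slope unidentifiable")
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  a <- (swxx * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (by - a - b * bx)^2)
  phi <- max(1, sqrt(rss / (J - 2)))
  se_a <- sqrt(swxx / det) * phi
  se_b <- sqrt(sw / det) * phi
  est <- .mr_estimate("egger", b, se_b, J, phi,
                      intercept = a, intercept_se = se_a)
  est
}

# weighted median of `x` with weights `w` via linear interpolation of
# the weighted empirical CDF at its midpoints
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The 50% point of the inverse-variance-weighted distribution of
#' per-variant ratio estimates, obtained by linear interpolation of the
#' weighted empirical CDF between order-statistic midpoints.  Consistent
#' as long as valid instruments carry at least half the weight, so up to
#' half the weight may come from invalid (pleiotropic) variants.  The
#' standard error is estimated by parametric bootstrap: exposure and
#' outcome betas are redrawn from their sampling distributions and the
#' estimator recomputed.
#'
#' @param dat Harmonized instrument table (at least 3 variants).
#' @param n_boot Bootstrap replicates, default 1000 (minimum 100).
#' @param seed RNG seed for the bootstrap; mandatory for
#'   reproducibility.
#' @return An \code{mr_estimate}.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed) {
  if (missing(seed)) stop("a bootstrap seed is required")
  stopifnot(n_boot >= 100)
  dat <- .mr_data(dat, 3L)
  J <- nrow(dat)
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  sx <- dat$se_exposure; sy <- dat$se_outcome
  ratio <- by / bx
  w <- bx^2 / sy^2            # inverse first-order ratio variances
  beta <- .weighted_median(ratio, w)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bxs <- stats::rnorm(J, bx, sx)
    bys <- stats::rnorm(J, by, sy)
    .weighted_median(bys / bxs, bxs^2 / sy^2)
  }, numeric(1))
  se <- stats::sd(boot)
  .mr_estimate("weighted_median", beta, se, J)
}

# Save/restore the global RNG state so seeded estimators do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# align an LD matrix to the rsids of a harmonized table and condition it
.omega <- function(dat, ld, ridge = 1e-10) {
  if (!all(dat$rsid %in% rownames(ld)))
    stop("LD matrix does not cover variant(s): ",
         paste(setdiff(dat$rsid, rownames(ld)), collapse = ", "))
  rho <- ld[dat$rsid, dat$rsid, drop = FALSE]
  sy <- dat$se_outcome
  om <- outer(sy, sy) * rho
  om <- om + diag(ridge * mean(diag(om)), nrow(om))
  ch <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(ch))
    stop("outcome covariance not positive-definite even after ridge ",
         "conditioning; prune the instrument set more aggressively")
  ch
}

#' Inverse-variance-weighted estimate with correlated instruments
#'
#' Generalized least squares version of [mr_ivw()] for cis instruments
#' in linkage disequilibrium.  The outcome covariance is
#' \eqn{\Omega_{jk} = \sigma_{Yj}\sigma_{Yk}\rho_{jk}} with signed LD
#' correlations \eqn{\rho}; the estimate is
#' \eqn{(x'\Omega^{-1}y)/(x'\Omega^{-1}x)} with standard error
#' \eqn{(x'\Omega^{-1}x)^{-1/2}} inflated by
#' \eqn{\phi = \max(1, \sqrt{q/(J-1)})}, \eqn{q} the GLS residual
#' quadratic form.  Solved via Cholesky factorization; reduces exactly
#' to [mr_ivw()] at identity LD.
#'
#' @param dat Harmonized instrument table.
#' @param ld Signed LD correlation matrix covering all variants.
#' @return An \code{mr_estimate}.
#' @export
mr_ivw_correlated <- function(dat, ld) {
  dat <- .mr_data(dat, 2L)
  J <- nrow(dat)
  ch <- .omega(dat, ld)
  # whiten: solve L z = v with Omega = L'L (chol gives upper R: Omega = R'R)
  xs <- backsolve(ch, dat$beta_exposure, transpose = TRUE)
  ys <- backsolve(ch, dat$beta_outcome, transpose = TRUE)
  sxx <- sum(xs^2)
  beta <- sum(xs * ys) / sxx
  se <- 1 / sqrt(sxx)
  q <- sum((ys - beta * xs)^2)
  phi <- max(1, sqrt(q / (J - 1)))
  .mr_estimate("ivw_correlated", beta, se * phi, J, phi)
}

#' MR-Egger with correlated instruments
#'
#' Generalized least squares version of [mr_egger()] with design
#' \eqn{(1, \beta_X)} and outcome covariance \eqn{\Omega} built from the
#' signed LD matrix.  Standard errors are inflated by
#' \eqn{\phi = \max(1, \sqrt{q/(J-2)})}.  Reduces exactly to
#' [mr_egger()] at identity LD.
#'
#' @inheritParams mr_ivw_correlated
#' @return An \code{mr_estimate} with intercept fields.
#' @export
mr_egger_correlated <- function(dat, ld) {
  dat <- .mr_data(dat, 3L, require_positive = TRUE)
  J <- nrow(dat)
  ch <- .omega(dat, ld)
  X <- cbind(1, dat$beta_exposure)
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, dat$beta_outcome, transpose = TRUE)
  xtx <- crossprod(Xs)
  coefs <- solve(xtx, crossprod(Xs, ys))
  resid <- ys - Xs %*% coefs
  q <- sum(resid^2)
  phi <- max(1, sqrt(q / (J - 2)))
  covm <- solve(xtx)
  .mr_estimate("egger_correlated", coefs[2], sqrt(covm[2, 2]) * phi, J, phi,
               intercept = coefs[1], intercept_se = sqrt(covm[1, 1]) * phi)
}

#' Odds-ratio-scale view of a causal estimate
#'
#' Exponentiates the log-odds estimate and its confidence bounds.
#' Rounding to two decimals happens only at presentation
#' ([format_or()]), never here.
#'
#' @param est An \code{mr_estimate}.
#' @return List with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{pvalue}, \code{method}.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  list(or = exp(est$beta), ci_low = exp(est$ci_low),
       ci_high = exp(est$ci_high), pvalue = est$pvalue,
       method = est$method)
}

#' Format an estimate as "OR (95% CI low-high)" at 2 decimals
#' @param est An \code{mr_estimate}.
#' @return Character scalar.
#' @export
format_or <- function(est) {
  or <- to_odds_ratio(est)
  sprintf("%.2f (%.2f-%.2f)", or$or, or$ci_low, or$ci_high)
}
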