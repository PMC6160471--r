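# Heterogeneity and pleiotropy diagnostics: the exact Q statistic with
# modified second-order weights, and the MR-PRESSO global / outlier /
# remove-retest workflow.

#' Exact heterogeneity statistic with modified second-order weights
#'
#' Cochran-type heterogeneity test that propagates uncertainty in both
#' the numerator and the denominator of the per-variant ratio estimates,
#' relaxing the no-measurement-error (NOME) assumption.  The statistic
#' is the minimum over the causal parameter \eqn{b} of
#' \deqn{Q(b) = \sum_j \frac{(\beta_{Yj} - b\,\beta_{Xj})^2}
#'                          {\sigma_{Yj}^2 + b^2 \sigma_{Xj}^2},}
#' found by bounded one-dimensional minimization (bracket ten times the
#' IVW estimate around it, tolerance 1e-10), and is referred to a
#' chi-square distribution with \eqn{J-1} degrees of freedom.  As the
#' exposure standard errors shrink to zero it reduces to the first-order
#' Cochran Q at the IVW estimate.
#'
#' @param dat Harmonized instrument table (at least 2 variants).
#' @return A \code{heterogeneity_report}: \code{q_prime}, \code{df},
#'   \code{pvalue}, \code{beta_at_min}.
#' @export
q_prime <- function(dat) {
  dat <- .mr_data(dat, 2L)
  J <- nrow(dat)
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  sx <- dat$se_exposure; sy <- dat$se_outcome
  qfun <- function(b) sum((by - b * bx)^2 / (sy^2 + b^2 * sx^2))
  b0 <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  half <- 10 * max(abs(b0), 0.1)
  opt <- stats::optimize(qfun, interval = c(b0 - half, b0 + half),
                         tol = 1e-10)
  # widen once if the minimum sits on the bracket boundary
  if (min(abs(opt$minimum - (b0 + c(-half, half)))) < 1e-6 * half) {
    half <- 100 * half
    opt <- stats::optimize(qfun, interval = c(b0 - half, b0 + half),
                           tol = 1e-10)
    if (min(abs(opt$minimum - (b0 + c(-half, half)))) < 1e-6 * half)
      stop("heterogeneity minimizer did not converge: minimum at bracket ",
           "boundary (b = ", format(opt$minimum), ", Q = ",
           format(opt$objective), ")")
  }
  structure(list(q_prime = opt$objective, df = J - 1L,
                 pvalue = stats::pchisq(opt$objective, J - 1L,
                                        lower.tail = FALSE),
                 beta_at_min = opt$minimum),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Q' = %.3f on %d df, p = %.3g (beta at minimum %.4f)\n",
              x$q_prime, x$df, x$pvalue, x$beta_at_min))
  invisible(x)
}

# leave-one-out IVW (fixed-effect, zero intercept) slopes via totals
.loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global heterogeneity test
#'
#' Compares the observed weighted residual sum of squares of all
#' variants around leave-one-out IVW regression lines with its
#' distribution under the no-pleiotropy null, obtained by parametric
#' simulation.  For each variant \eqn{j} the leave-one-out slope
#' \eqn{\hat\beta_{(-j)}} is computed and the observed statistic is
#' \eqn{RSS = \sum_j (\beta_{Yj} - \hat\beta_{(-j)}\beta_{Xj})^2
#' \sigma_{Yj}^{-2}}.  Each replicate redraws
#' \eqn{\beta_{Xj}^* \sim N(\beta_{Xj}, \sigma_{Xj}^2)} and
#' \eqn{\beta_{Yj}^* \sim N(\hat\beta_{(-j)}\beta_{Xj}, \sigma_{Yj}^2)}
#' and recomputes the statistic; the p-value is empirical with an
#' add-one correction, so it can never be exactly zero.
#'
#' @param dat Harmonized instrument table (at least 4 variants).
#' @param n_sim Number of simulation replicates, default 1000.
#' @param seed RNG seed; mandatory.
#' @return A \code{presso_global} object: \code{rss_observed},
#'   \code{global_p}, \code{n_sim}, \code{seed}, plus the per-variant
#'   observed and simulated residual distances reused by
#'   [presso_outliers()].
#' @export
presso_global <- function(dat, n_sim = 1000, seed) {
  if (missing(seed)) stop("a simulation seed is required")
  dat <- .mr_data(dat, 4L)
  stopifnot(n_sim >= 100)
  J <- nrow(dat)
  bx <- dat$beta_exposure; by <- dat$beta_outcome
  sx <- dat$se_exposure; sy <- dat$se_outcome
  w <- 1 / sy^2
  b_loo <- .loo_slopes(bx, by, w)
  d_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(d_obs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # J x n_sim matrices of simulated exposure/outcome betas
  bxs <- matrix(stats::rnorm(J * n_sim, bx, sx), J, n_sim)
  bys <- matrix(stats::rnorm(J * n_sim, b_loo * bx, sy), J, n_sim)
  # per-replicate leave-one-out slopes (weights fixed at 1/sy^2)
  wb <- w * bxs
  sxy <- colSums(wb * bys)
  sxx <- colSums(wb * bxs)
  b_loo_s <- (rep(1, J) %o% sxy - wb * bys) /
             (rep(1, J) %o% sxx - wb * bxs)
  d_sim <- w * (bys - b_loo_s * bxs)^2
  rss_sim <- colSums(d_sim)
  structure(list(rss_observed = rss_obs,
                 global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
                 n_sim = n_sim, seed = seed,
                 rsid = if ("rsid" %in% names(dat)) dat$rsid
                        else as.character(seq_len(J)),
                 distance_observed = d_obs,
                 distance_simulated = d_sim),
            class = "presso_global")
}

#' @export
print.presso_global <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_p, x$n_sim))
  invisible(x)
}

#' MR-PRESSO per-variant outlier test
#'
#' Compares each variant's observed weighted squared residual distance
#' to its simulated null distribution from [presso_global()]; variants
#' with empirical p below \code{alpha_outlier} are flagged as outliers.
#' P-values carry the add-one correction and are never exactly zero.
#'
#' @param dat Harmonized instrument table.
#' @param n_sim,seed Passed to [presso_global()] when \code{global} is
#'   not supplied.
#' @param alpha_outlier Per-variant flagging threshold, default 0.05 (no
#'   multiplicity correction; pass e.g. \code{0.05/J} for Bonferroni).
#' @param global Optional precomputed [presso_global()] result for the
#'   same data and seed.
#' @return List with \code{outliers} (rsids), \code{pvalues} (named) and
#'   \code{alpha_outlier}.
#' @export
presso_outliers <- function(dat, n_sim = 1000, seed, alpha_outlier = 0.05,
                            global = NULL) {
  if (is.null(global)) global <- presso_global(dat, n_sim, seed)
  stopifnot(inherits(global, "presso_global"))
  p <- (1 + rowSums(global$distance_simulated >=
                    global$distance_observed)) / (global$n_sim + 1)
  names(p) <- global$rsid
  out <- names(p)[p < alpha_outlier]
  if (length(out) == length(p))
    stop("all variants flagged as outliers: no stable regression remains")
  list(outliers = out, pvalues = p, alpha_outlier = alpha_outlier)
}

#' MR-PRESSO workflow: global test, outlier removal, retest
#'
#' Runs the three-step procedure: (i) global heterogeneity test; (ii) if
#' significant at \code{alpha_global}, identify and remove per-variant
#' outliers; (iii) retest heterogeneity on the remaining variants to
#' check whether removal resolved it.  The adjusted causal estimate is
#' the IVW estimate on the non-outlier variants.
#'
#' @param dat Harmonized instrument table (at least 4 variants).
#' @param n_sim Simulation replicates, default 1000.
#' @param seed RNG seed; mandatory.
#' @param alpha_outlier Per-variant outlier threshold, default 0.05.
#' @param alpha_global Gate for the outlier step, default 0.05.
#' @param effects_model Passed to [mr_ivw()] for both estimates.
#' @return A \code{presso_report}.
#' @export
presso_workflow <- function(dat, n_sim = 1000, seed, alpha_outlier = 0.05,
                            alpha_global = 0.05,
                            effects_model = "multiplicative_random") {
  dat <- .mr_data(dat, 4L)
  glob <- presso_global(dat, n_sim, seed)
  raw <- mr_ivw(dat, effects_model)
  q_pre <- q_prime(dat)
  outliers <- character(0)
  pvalues <- NULL
  adj <- raw
  q_post <- q_pre
  if (glob$global_p < alpha_global) {
    ot <- presso_outliers(dat, global = glob, alpha_outlier = alpha_outlier)
    outliers <- ot$outliers
    pvalues <- ot$pvalues
    if (length(outliers) > 0) {
      keep <- dat[!(dat$rsid %in% outliers), , drop = FALSE]
      adj <- mr_ivw(keep, effects_model)
      q_post <- q_prime(keep)
    }
  }
  structure(list(rss_observed = glob$rss_observed,
                 global_p = glob$global_p,
                 outlier_pvalues = pvalues,
                 outliers = outliers,
                 raw_estimate = raw,
                 adjusted_estimate = adj,
                 q_prime_before = q_pre,
                 q_prime_after = q_post,
                 n_sim = n_sim, seed = seed),
            class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.4g; %d outlier(s)%s\n",
              x$global_p, length(x$outliers),
              if (length(x$outliers) > 0)
                paste0(" (", paste(x$outliers, collapse = ", "), ")")
              else ""))
  cat("adjusted "); print(x$adjusted_estimate)
  cat(sprintf("Q' before: p = %.3g; after: p = %.3g\n",
              x$q_prime_before$pvalue, x$q_prime_after$pvalue))
  invisible(x)
}

#' Serialize a presso_report to JSON
#' @param report A \code{presso_report}.
#' @param path Output path.
#' @export
write_presso_report <- function(report, path) {
  flat <- list(
    rss_observed = report$rss_observed,
    global_p = report$global_p,
    outliers = report$outliers,
    outlier_pvalues = as.list(report$outlier_pvalues),
    raw_estimate = unclass(report$raw_estimate),
    adjusted_estimate = unclass(report$adjusted_estimate),
    q_prime_before = unclass(report$q_prime_before),
    q_prime_after = unclass(report$q_prime_after),
    n_sim = report$n_sim, seed = report$seed)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
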