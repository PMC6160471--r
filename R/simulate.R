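# Synthetic two-sample GWAS summary statistics with known causal truth.
#
# Default sample sizes mirror the scale of the largest available lipid
# (about 188,577 persons) and breast-cancer case-control (about 122,977
# cases / 105,974 controls) GWAS meta-analyses, so standard errors and
# instrument strengths on synthetic data are realistic for this class
# of study.

.N_EXPOSURE_DEFAULT <- 188577
.N_CASES_DEFAULT <- 122977
.N_CONTROLS_DEFAULT <- 105974

# Deterministic per-table sub-seed derived from the global seed, so each
# table draws from its own stream and generating one table does not
# disturb another.  Kept below 2^31.
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2000003) * 1000 + offset)
}

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

# non-palindromic single-base allele pairs
.ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
.PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

.sumstat_frame <- function(rsid, ea, oa, eaf, beta, se, n) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pvalue = pmin(1, 2 * stats::pnorm(-abs(beta / se))),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate a two-sample MR dataset with known truth
#'
#' Generates paired exposure and outcome summary-statistic tables for
#' \code{J} independent variants under the generative model
#' \deqn{\Gamma_j = \theta\,\gamma_j + \alpha_j,}
#' where \eqn{\gamma_j} are true per-SD exposure effects,
#' \eqn{\alpha_j} per-variant horizontal-pleiotropy effects on the
#' outcome and \eqn{\theta} the causal log-odds per SD.  Effect-allele
#' frequencies are uniform on (0.05, 0.95); exposure effects are
#' N(0.08, 0.03^2) clipped to be positive; standard errors follow the
#' standard GWAS approximations
#' \eqn{\sigma_{Xj} = 1/\sqrt{2 p_j (1-p_j) n_{exp}}} and
#' \eqn{\sigma_{Yj} = 1/\sqrt{2 p_j (1-p_j) n_{eff}}} with
#' \eqn{n_{eff} = n_{cases} n_{controls} / (n_{cases}+n_{controls})};
#' observed betas are drawn normally around the truth.  Pleiotropy
#' modes: \code{"none"} (all \eqn{\alpha_j = 0}), \code{"balanced"}
#' (\eqn{\alpha_j \sim N(0, s^2)}), \code{"directional"}
#' (\eqn{\alpha_j \sim N(\mu, s^2)}), \code{"outlier"} (a few spiked
#' entries of \code{outlier_scale} outcome standard errors each).
#'
#' @param J Number of variants (>= 2).
#' @param theta True causal log-odds per SD.
#' @param pleiotropy_mode One of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"outlier"}.
#' @param pleiotropy_scale Standard deviation s of the pleiotropy law
#'   (balanced/directional), default 0.01.
#' @param pleiotropy_mean Mean \eqn{\mu} of directional pleiotropy,
#'   default 0.05.
#' @param n_outliers Number of spiked variants in outlier mode,
#'   default 1.
#' @param outlier_scale Spike magnitude in units of the variant's
#'   outcome standard error, default 10.
#' @param n_exposure,n_cases,n_controls Sample sizes; defaults mimic
#'   large lipid and breast-cancer consortium meta-analyses.
#' @param seed Global seed; mandatory.  Each table draws from its own
#'   derived sub-stream.
#' @param allow_palindromic If TRUE a fraction of variants get A/T or
#'   C/G allele pairs; default FALSE so harmonization retains all
#'   variants.
#' @return List with \code{exposure}, \code{outcome} (summary-statistic
#'   data frames) and \code{truth} (a \code{synthetic_truth} list:
#'   theta, gamma, alpha, outcome truth Gamma, outlier indices,
#'   frequencies, standard errors, sample sizes, seed).
#' @export
simulate_instruments <- function(J, theta = 0,
                                 pleiotropy_mode = c("none", "balanced",
                                                     "directional", "outlier"),
                                 pleiotropy_scale = 0.01,
                                 pleiotropy_mean = 0.05,
                                 n_outliers = 1, outlier_scale = 10,
                                 n_exposure = .N_EXPOSURE_DEFAULT,
                                 n_cases = .N_CASES_DEFAULT,
                                 n_controls = .N_CONTROLS_DEFAULT,
                                 seed, allow_palindromic = FALSE) {
  if (missing(seed)) stop("a seed is required")
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(J >= 2, n_exposure > 0, n_cases > 0, n_controls > 0)

  frame <- .with_seed(.substream(seed, 1L), {
    p <- stats::runif(J, 0.05, 0.95)
    gamma <- pmax(stats::rnorm(J, 0.08, 0.03), 0.01)
    pairs <- if (allow_palindromic)
      rbind(.ALLELE_PAIRS, .PALINDROMIC_PAIRS) else .ALLELE_PAIRS
    pick <- sample(nrow(pairs), J, replace = TRUE)
    alpha <- switch(pleiotropy_mode,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, pleiotropy_scale),
      directional = stats::rnorm(J, pleiotropy_mean, pleiotropy_scale),
      outlier = rep(0, J))
    outlier_idx <- integer(0)
    if (pleiotropy_mode == "outlier")
      outlier_idx <- sort(sample(J, n_outliers))
    list(p = p, gamma = gamma, ea = pairs[pick, 1], oa = pairs[pick, 2],
         alpha = alpha, outlier_idx = outlier_idx)
  })
  p <- frame$p; gamma <- frame$gamma; alpha <- frame$alpha
  n_eff <- n_cases * n_controls / (n_cases + n_controls)
  sx <- 1 / sqrt(2 * p * (1 - p) * n_exposure)
  sy <- 1 / sqrt(2 * p * (1 - p) * n_eff)
  if (pleiotropy_mode == "outlier")
    alpha[frame$outlier_idx] <- outlier_scale * sy[frame$outlier_idx]
  Gamma <- theta * gamma + alpha

  rsid <- sprintf("rs%06d", seq_len(J))
  bx <- .with_seed(.substream(seed, 2L), stats::rnorm(J, gamma, sx))
  by <- .with_seed(.substream(seed, 3L), stats::rnorm(J, Gamma, sy))

  truth <- structure(list(theta = theta, gamma = gamma, alpha = alpha,
                          Gamma = Gamma, pleiotropy_mode = pleiotropy_mode,
                          outlier_indices = frame$outlier_idx,
                          outlier_rsids = rsid[frame$outlier_idx],
                          eaf = p, sigma_x = sx, sigma_y = sy,
                          n_exposure = n_exposure, n_cases = n_cases,
                          n_controls = n_controls, seed = seed),
                     class = "synthetic_truth")
  list(exposure = .sumstat_frame(rsid, frame$ea, frame$oa, p, bx, sx,
                                 n_exposure),
       outcome = .sumstat_frame(rsid, frame$ea, frame$oa, p, by, sy,
                                n_cases + n_controls),
       truth = truth)
}

#' Simulate a correlated multi-lipid variant panel
#'
#' Builds a panel of variants with association statistics for three
#' lipid fractions (LDL-C, HDL-C, triglycerides) and planted structure:
#' each variant belongs to a class that determines which lipids it truly
#' affects (one lipid, a pair, or all three), and a 3x3 loading matrix
#' mixes those latent effects across the observed lipids.  The planted
#' classes make comprehensive and restrictive instrument selection
#' checkable against known truth.
#'
#' @param J_total Number of variants.
#' @param loading 3x3 matrix (rows/cols ordered ldl, hdl, tg) applied to
#'   the latent per-lipid effects; identity (default) gives
#'   lipid-specific variants no cross-association.
#' @param classes Optional character vector of length \code{J_total}
#'   with values among \code{"ldl"}, \code{"hdl"}, \code{"tg"},
#'   \code{"ldl_hdl"}, \code{"ldl_tg"}, \code{"hdl_tg"}, \code{"all"};
#'   by default classes are sampled uniformly from the three specific
#'   and three pairwise-shared classes.
#' @param effect_size Mean latent per-SD effect, default 0.1.
#' @param n_exposure Exposure sample size (drives standard errors).
#' @param seed Global seed; mandatory.
#' @return List with \code{panel} (data frame: rsid, eaf and
#'   \code{beta_}/\code{se_}/\code{p_} columns per lipid) and
#'   \code{truth} (classes and true effect matrix).
#' @export
simulate_multilipid <- function(J_total, loading = diag(3), classes = NULL,
                                effect_size = 0.1,
                                n_exposure = .N_EXPOSURE_DEFAULT, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(J_total >= 1, all(dim(loading) == c(3, 3)))
  valid <- c("ldl", "hdl", "tg", "ldl_hdl", "ldl_tg", "hdl_tg", "all")
  membership <- list(ldl = "ldl", hdl = "hdl", tg = "tg",
                     ldl_hdl = c("ldl", "hdl"), ldl_tg = c("ldl", "tg"),
                     hdl_tg = c("hdl", "tg"), all = .LIPIDS)
  .with_seed(.substream(seed, 4L), {
    if (is.null(classes))
      classes <- sample(valid[1:6], J_total, replace = TRUE)
    stopifnot(length(classes) == J_total, all(classes %in% valid))
    p <- stats::runif(J_total, 0.05, 0.95)
    sigma <- 1 / sqrt(2 * p * (1 - p) * n_exposure)
    pick <- sample(nrow(.ALLELE_PAIRS), J_total, replace = TRUE)
    # latent effect vector per variant: nonzero on member lipids
    u <- matrix(0, J_total, 3, dimnames = list(NULL, .LIPIDS))
    for (j in seq_len(J_total)) {
      mem <- membership[[classes[j]]]
      u[j, mem] <- pmax(stats::rnorm(length(mem), effect_size,
                                     effect_size / 5), effect_size / 10)
    }
    mu <- u %*% t(loading)
    beta <- mu + matrix(stats::rnorm(J_total * 3, 0, sigma), J_total, 3)
    panel <- data.frame(rsid = sprintf("rs%06d", seq_len(J_total)),
                        effect_allele = .ALLELE_PAIRS[pick, 1],
                        other_allele = .ALLELE_PAIRS[pick, 2],
                        eaf = p, stringsAsFactors = FALSE)
    for (k in seq_along(.LIPIDS)) {
      l <- .LIPIDS[k]
      panel[[paste0("beta_", l)]] <- beta[, k]
      panel[[paste0("se_", l)]] <- sigma
      panel[[paste0("p_", l)]] <-
        pmin(1, 2 * stats::pnorm(-abs(beta[, k] / sigma)))
    }
    list(panel = panel,
         truth = structure(list(classes = classes, latent_effects = u,
                                mean_effects = mu, loading = loading,
                                eaf = p, sigma = sigma, seed = seed),
                           class = "synthetic_truth"))
  })
}

#' Simulate a complete synthetic two-sample MR study
#'
#' Combines [simulate_multilipid()] with outcome generation so the full
#' lipid pipeline (selection, harmonization, estimation, diagnostics)
#' can run end-to-end against known truth.  Each outcome's true
#' per-variant log-odds effect is
#' \eqn{\Gamma_j = \sum_l \theta_l \mu_{jl}}, the lipid-mediated causal
#' contribution summed over the three lipid fractions, with observed
#' outcome betas drawn normally around it.
#'
#' @param J_total Number of panel variants.
#' @param thetas Named list: one numeric vector
#'   \code{c(ldl = , hdl = , tg = )} of causal log-odds-per-SD effects
#'   per outcome.
#' @param classes,loading,effect_size,n_exposure Passed to
#'   [simulate_multilipid()].
#' @param n_cases,n_controls Outcome sample sizes (applied to every
#'   outcome).
#' @param seed Global seed; mandatory.
#' @return List with \code{panel}, \code{outcomes} (named list of
#'   outcome tables) and \code{truth}.
#' @export
simulate_study <- function(J_total, thetas, classes = NULL,
                           loading = diag(3), effect_size = 0.1,
                           n_exposure = .N_EXPOSURE_DEFAULT,
                           n_cases = .N_CASES_DEFAULT,
                           n_controls = .N_CONTROLS_DEFAULT, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(is.list(thetas), length(thetas) >= 1,
            !is.null(names(thetas)),
            all(vapply(thetas, function(t) all(.LIPIDS %in% names(t)),
                       logical(1))))
  ml <- simulate_multilipid(J_total, loading, classes, effect_size,
                            n_exposure, seed)
  panel <- ml$panel
  mu <- ml$truth$mean_effects      # J x 3 true lipid effects
  p <- ml$truth$eaf
  n_eff <- n_cases * n_controls / (n_cases + n_controls)
  sy <- 1 / sqrt(2 * p * (1 - p) * n_eff)
  outcomes <- list()
  Gammas <- list()
  for (k in seq_along(thetas)) {
    oname <- names(thetas)[k]
    Gamma <- as.vector(mu %*% thetas[[k]][.LIPIDS])
    by <- .with_seed(.substream(seed, 10L + k),
                     stats::rnorm(J_total, Gamma, sy))
    outcomes[[oname]] <- .sumstat_frame(panel$rsid, panel$effect_allele,
                                        panel$other_allele, p, by, sy,
                                        n_cases + n_controls)
    Gammas[[oname]] <- Gamma
  }
  truth <- ml$truth
  truth$thetas <- thetas
  truth$Gamma <- Gammas
  truth$sigma_y <- sy
  truth$n_cases <- n_cases
  truth$n_controls <- n_controls
  list(panel = panel, outcomes = outcomes, truth = truth)
}

#' Simulate a cis gene-region LD block with correlated instruments
#'
#' Generates an autoregressive LD structure
#' \eqn{\rho_{jk} = r^{|j-k|}} (positive-definite by construction) over
#' \code{J} cis variants and draws the observed exposure and outcome
#' betas jointly with covariance built from that correlation, mimicking
#' summary statistics for variants in a single gene region.  The true
#' causal model is the same as in [simulate_instruments()] with no
#' pleiotropy.
#'
#' @param J Number of variants in the block.
#' @param decay_rho Autoregressive correlation parameter in [0, 1).
#' @param theta True causal log-odds per SD.
#' @param n_exposure,n_cases,n_controls Sample sizes.
#' @param seed Global seed; mandatory.
#' @return List with \code{exposure}, \code{outcome}, \code{ld} (signed
#'   correlation matrix with rsid dimnames) and \code{truth}.
#' @export
simulate_ld_block <- function(J, decay_rho, theta = 0,
                              n_exposure = .N_EXPOSURE_DEFAULT,
                              n_cases = .N_CASES_DEFAULT,
                              n_controls = .N_CONTROLS_DEFAULT, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(J >= 2, decay_rho >= 0, decay_rho < 1)
  rho <- decay_rho^abs(outer(seq_len(J), seq_len(J), "-"))
  rsid <- sprintf("rs%06d", seq_len(J))
  dimnames(rho) <- list(rsid, rsid)

  frame <- .with_seed(.substream(seed, 5L), {
    p <- stats::runif(J, 0.05, 0.95)
    gamma <- pmax(stats::rnorm(J, 0.08, 0.03), 0.01)
    pick <- sample(nrow(.ALLELE_PAIRS), J, replace = TRUE)
    list(p = p, gamma = gamma,
         ea = .ALLELE_PAIRS[pick, 1], oa = .ALLELE_PAIRS[pick, 2])
  })
  p <- frame$p; gamma <- frame$gamma
  n_eff <- n_cases * n_controls / (n_cases + n_controls)
  sx <- 1 / sqrt(2 * p * (1 - p) * n_exposure)
  sy <- 1 / sqrt(2 * p * (1 - p) * n_eff)
  Gamma <- theta * gamma
  bx <- .with_seed(.substream(seed, 6L),
                   as.vector(MASS::mvrnorm(1, gamma, outer(sx, sx) * rho)))
  by <- .with_seed(.substream(seed, 7L),
                   as.vector(MASS::mvrnorm(1, Gamma, outer(sy, sy) * rho)))
  truth <- structure(list(theta = theta, gamma = gamma, Gamma = Gamma,
                          decay_rho = decay_rho, eaf = p,
                          sigma_x = sx, sigma_y = sy,
                          n_exposure = n_exposure, n_cases = n_cases,
                          n_controls = n_controls, seed = seed),
                     class = "synthetic_truth")
  list(exposure = .sumstat_frame(rsid, frame$ea, frame$oa, p, bx, sx,
                                 n_exposure),
       outcome = .sumstat_frame(rsid, frame$ea, frame$oa, p, by, sy,
                                n_cases + n_controls),
       ld = rho,
       truth = truth)
}

#' Write a summary-statistic table in the package's TSV dialect
#' @param x Summary-statistic data frame.
#' @param path Output path.
#' @export
write_summary_stats <- function(x, path) {
  y <- x
  for (cn in names(y))            # full precision so re-reading is lossless
    if (is.numeric(y[[cn]])) y[[cn]] <- sprintf("%.17g", y[[cn]])
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic_truth object as a JSON sidecar
#' @param truth A \code{synthetic_truth}.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
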