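# Independent oracles and small fixture builders used across the suite.

# zero-intercept weighted least squares via stats::lm (independent of the
# package's closed-form IVW)
oracle_ivw <- function(bx, by, sy, effects_model = "multiplicative_random") {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ 0 + bx, weights = w)
  sigma <- summary(fit)$sigma
  se_fixed <- sqrt(diag(stats::vcov(fit)))[[1]] / sigma
  phi <- if (effects_model == "multiplicative_random") max(1, sigma) else 1
  list(beta = unname(stats::coef(fit)[[1]]), se = se_fixed * phi, phi = phi)
}

# weighted regression with intercept via stats::lm
oracle_egger <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sigma <- summary(fit)$sigma
  ses <- sqrt(diag(stats::vcov(fit))) / sigma * max(1, sigma)
  list(intercept = unname(stats::coef(fit)[[1]]),
       beta = unname(stats::coef(fit)[[2]]),
       intercept_se = unname(ses[1]), se = unname(ses[2]))
}

# GLS by explicit matrix inversion (the implementation factorizes instead)
oracle_gls <- function(bx, by, sy, rho, with_intercept) {
  om <- outer(sy, sy) * rho
  om <- om + diag(1e-10 * mean(diag(om)), nrow(om))
  oi <- solve(om)
  J <- length(bx)
  if (with_intercept) {
    X <- cbind(1, bx)
    xtx <- t(X) %*% oi %*% X
    coefs <- solve(xtx, t(X) %*% oi %*% by)
    r <- by - X %*% coefs
    q <- drop(t(r) %*% oi %*% r)
    phi <- max(1, sqrt(q / (J - 2)))
    covm <- solve(xtx)
    list(intercept = coefs[1], beta = coefs[2],
         intercept_se = sqrt(covm[1, 1]) * phi,
         se = sqrt(covm[2, 2]) * phi)
  } else {
    sxx <- drop(t(bx) %*% oi %*% bx)
    beta <- drop(t(bx) %*% oi %*% by) / sxx
    q <- drop(t(by - beta * bx) %*% oi %*% (by - beta * bx))
    phi <- max(1, sqrt(q / (J - 1)))
    list(beta = beta, se = phi / sqrt(sxx))
  }
}

# brute-force scan of the weighted empirical CDF midpoints
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  for (j in seq_len(n - 1)) {
    if (s[j] <= 0.5 && 0.5 <= s[j + 1]) {
      f <- (0.5 - s[j]) / (s[j + 1] - s[j])
      return(x[j] + f * (x[j + 1] - x[j]))
    }
  }
  stop("unreachable")
}

# harmonized-format data frame straight from known effect vectors
make_dat <- function(bx, by, sx, sy, rsid = sprintf("rs%03d", seq_along(bx))) {
  data.frame(rsid = rsid, beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy,
             stringsAsFactors = FALSE)
}

# random harmonized dataset for oracle comparisons
random_dat <- function(J, seed) {
  set.seed(seed)
  make_dat(bx = runif(J, 0.02, 0.3), by = rnorm(J, 0.01, 0.05),
           sx = runif(J, 0.001, 0.01), sy = runif(J, 0.005, 0.05))
}

# small valid association table for IO tests
make_assoc <- function(n = 3, seed = 1) {
  set.seed(seed)
  data.frame(rsid = sprintf("rs%d", seq_len(n)),
             effect_allele = sample(c("A", "G", "C"), n, TRUE),
             other_allele = rep("T", n),
             eaf = runif(n, 0.1, 0.9),
             beta = rnorm(n, 0, 0.1),
             se = runif(n, 0.01, 0.05),
             pvalue = runif(n, 1e-10, 1),
             n = rep(1000, n), stringsAsFactors = FALSE)
}
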