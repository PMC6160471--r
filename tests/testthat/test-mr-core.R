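test_that("Wald ratios and both standard-error orders match the formulas", {
  d <- make_dat(bx = 0.5, by = 0.05, sx = 0.01, sy = 0.02)
  wr <- wald_ratio(d)
  expect_equal(wr$ratio, 0.10)
  expect_equal(wr$se_first, 0.04)

  # zero outcome effect: null ratio with positive uncertainty
  d0 <- make_dat(bx = 0.5, by = 0, sx = 0.01, sy = 0.02)
  wr0 <- wald_ratio(d0)
  expect_equal(wr0$ratio, 0)
  expect_gt(wr0$se_first, 0)

  # second-order se equals the delta-method expansion, re-evaluated here
  for (s in 1:10) {
    d <- random_dat(8, seed = s)
    wr <- wald_ratio(d)
    expect_equal(wr$se_second,
                 sqrt(d$se_outcome^2 / d$beta_exposure^2 +
                      d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4),
                 tolerance = 1e-12)
    expect_true(all(wr$se_second >= wr$se_first))
  }
  expect_error(wald_ratio(make_dat(0, 0.1, 0.01, 0.02)),
               "non-informative")
})

test_that("IVW equals independent zero-intercept weighted least squares", {
  for (s in 1:20) {
    d <- random_dat(10, seed = 100 + s)
    for (em in c("fixed", "multiplicative_random")) {
      got <- mr_ivw(d, em)
      ora <- oracle_ivw(d$beta_exposure, d$beta_outcome, d$se_outcome, em)
      expect_equal(got$beta, ora$beta, tolerance = 1e-10)
      expect_equal(got$se, ora$se, tolerance = 1e-10)
      expect_equal(got$phi, ora$phi, tolerance = 1e-10)
    }
  }
})

test_that("a single variant degrades IVW to the Wald ratio", {
  d <- make_dat(0.2, 0.03, 0.01, 0.02)
  expect_warning(est <- mr_ivw(d), "single variant")
  wr <- wald_ratio(d)
  expect_equal(est$beta, wr$ratio)
  expect_equal(est$se, wr$se_first)
})

test_that("Egger matches the weighted-regression oracle and fits exact
           lines with phi = 1", {
  for (s in 1:20) {
    d <- random_dat(10, seed = 200 + s)
    got <- mr_egger(d)
    ora <- oracle_egger(d$beta_exposure, d$beta_outcome, d$se_outcome)
    expect_equal(got$beta, ora$beta, tolerance = 1e-10)
    expect_equal(got$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(got$se, ora$se, tolerance = 1e-10)
    expect_equal(got$intercept_se, ora$intercept_se, tolerance = 1e-10)
  }
  # data exactly on a line: intercept and slope recovered, no inflation
  bx <- c(0.1, 0.2, 0.3, 0.4)
  d <- make_dat(bx, by = 0.02 + 0.5 * bx, sx = 0.01, sy = c(1, 2, 3, 4) / 100)
  got <- mr_egger(d)
  expect_equal(got$intercept, 0.02, tolerance = 1e-12)
  expect_equal(got$beta, 0.5, tolerance = 1e-12)
  expect_equal(got$phi, 1)

  expect_error(mr_egger(make_dat(c(0.1, 0.2), c(0, 0), 0.01, 0.02)),
               "at least 3")
  expect_error(mr_egger(make_dat(c(0.1, -0.2, 0.3), c(0, 0, 0), 0.01, 0.02)),
               "increasing allele")
  expect_error(mr_egger(make_dat(c(0.1, 0.1, 0.1), c(0, 0, 0), 0.01, 0.02)),
               "unidentifiable")
})

test_that("weighted median interpolates the weighted CDF and matches the
           brute-force scan", {
  # odd count, uniform weights: plain midpoint
  d <- make_dat(bx = c(1, 1, 1), by = c(1, 2, 9), sx = 0, sy = 1)
  est <- mr_weighted_median(d, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2)

  for (s in 1:20) {
    d <- random_dat(9, seed = 300 + s)
    got <- mr_weighted_median(d, n_boot = 100, seed = s)
    ratio <- d$beta_outcome / d$beta_exposure
    w <- d$beta_exposure^2 / d$se_outcome^2
    expect_equal(got$beta, oracle_weighted_median(ratio, w),
                 tolerance = 1e-10)
  }
  expect_error(mr_weighted_median(random_dat(5, 1), n_boot = 100),
               "seed")
})

test_that("weighted median bootstrap is seed-reproducible", {
  d <- random_dat(12, seed = 7)
  a <- mr_weighted_median(d, n_boot = 200, seed = 5)
  b <- mr_weighted_median(d, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(d, n_boot = 200, seed = 6)
  expect_false(identical(a$se, c2$se))
})

test_that("correlated-instrument estimators match an explicit-inverse GLS
           solve and reduce to the uncorrelated forms at identity LD", {
  for (s in 1:10) {
    sim <- simulate_ld_block(8, 0.6, theta = 0.1, seed = 400 + s)
    d <- retained_instruments(harmonize(sim$exposure, sim$outcome))
    got_i <- mr_ivw_correlated(d, sim$ld)
    ora_i <- oracle_gls(d$beta_exposure, d$beta_outcome, d$se_outcome,
                        sim$ld[d$rsid, d$rsid], with_intercept = FALSE)
    expect_equal(got_i$beta, ora_i$beta, tolerance = 1e-10)
    expect_equal(got_i$se, ora_i$se, tolerance = 1e-10)
    got_e <- mr_egger_correlated(d, sim$ld)
    ora_e <- oracle_gls(d$beta_exposure, d$beta_outcome, d$se_outcome,
                        sim$ld[d$rsid, d$rsid], with_intercept = TRUE)
    expect_equal(got_e$beta, ora_e$beta, tolerance = 1e-10)
    expect_equal(got_e$intercept, ora_e$intercept, tolerance = 1e-10)
    expect_equal(got_e$se, ora_e$se, tolerance = 1e-10)
  }

  d <- random_dat(10, seed = 44)
  eye <- diag(10); dimnames(eye) <- list(d$rsid, d$rsid)
  plain <- mr_ivw(d)
  corr <- mr_ivw_correlated(d, eye)
  expect_equal(corr$beta, plain$beta, tolerance = 1e-8)
  expect_equal(corr$se, plain$se, tolerance = 1e-8)
  pe <- mr_egger(d); ce <- mr_egger_correlated(d, eye)
  expect_equal(ce$beta, pe$beta, tolerance = 1e-8)
  expect_equal(ce$intercept, pe$intercept, tolerance = 1e-8)
  expect_equal(ce$se, pe$se, tolerance = 1e-8)
})

test_that("a near-duplicated variant does not double-count evidence", {
  d <- random_dat(6, seed = 55)
  base <- mr_ivw_correlated(d, {
    m <- diag(6); dimnames(m) <- list(d$rsid, d$rsid); m })
  d2 <- rbind(d, transform(d[6, ], rsid = "rs_dup"))
  m2 <- diag(7); m2[6, 7] <- m2[7, 6] <- 1 - 1e-9
  dimnames(m2) <- list(d2$rsid, d2$rsid)
  dup <- mr_ivw_correlated(d2, m2)
  expect_equal(dup$beta, base$beta, tolerance = 1e-3)
  expect_equal(dup$se, base$se, tolerance = 0.05)
})

test_that("estimators are equivariant under rescaling of the exposure", {
  d <- random_dat(10, seed = 66)
  for (c_scale in c(0.5, 2, 10)) {
    ds <- transform(d, beta_exposure = beta_exposure * c_scale,
                    se_exposure = se_exposure * c_scale)
    expect_equal(mr_ivw(ds)$beta, mr_ivw(d)$beta / c_scale,
                 tolerance = 1e-10)
    expect_equal(mr_egger(ds)$beta, mr_egger(d)$beta / c_scale,
                 tolerance = 1e-10)
    a <- mr_weighted_median(ds, 100, seed = 2)
    b <- mr_weighted_median(d, 100, seed = 2)
    expect_equal(a$beta, b$beta / c_scale, tolerance = 1e-10)
  }
})

test_that("odds-ratio conversion exponentiates and brackets the estimate", {
  d <- random_dat(10, seed = 77)
  est <- mr_ivw(d)
  or <- to_odds_ratio(est)
  expect_equal(or$or, exp(est$beta))
  expect_equal(or$ci_low, exp(est$beta - 1.96 * est$se), tolerance = 1e-3)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)

  null <- est; null$beta <- 0; null$ci_low <- -0.01; null$ci_high <- 0.01
  expect_equal(to_odds_ratio(null)$or, 1)
  expect_match(format_or(est), "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}-\\d+\\.\\d{2}\\)$")
})
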