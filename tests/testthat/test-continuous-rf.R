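# continuous risk factor discretisation, observed bin, variance, bin count

height_rf <- function(n = 5L) continuous_rf("height", 162.81, 6.452,
                                            0.10130, n)

test_that("bin masses follow Binomial(n-1, 1/2)", {
  for (n in c(2L, 5L, 9L)) {
    b <- discretise_rf(height_rf(), n)
    expect_equal(b$mass, stats::dbinom(0:(n - 1L), n - 1L, 0.5),
                 tolerance = 1e-12)
  }
  expect_equal(discretise_rf(height_rf(), 5L)$mass,
               c(1, 4, 6, 4, 1) / 16, tolerance = 1e-12)
})

test_that("a null effect gives RR 1 in every bin", {
  rf0 <- continuous_rf("flat", 162.81, 6.452, 0)
  b <- discretise_rf(rf0, 5L)
  expect_equal(b$rr, rep(1, 5), tolerance = 1e-12)
  expect_equal(rr_variance(rf0), 0)
  expect_equal(rr_variance(b), 0, tolerance = 1e-12)
})

test_that("per-bin RRs match a dense Riemann-sum oracle", {
  rf <- height_rf()
  b <- discretise_rf(rf, 5L)
  x <- seq(rf$mean - 8 * rf$sd, rf$mean + 8 * rf$sd, length.out = 1e6)
  w <- stats::dnorm(x, rf$mean, rf$sd)
  rr <- exp(rf$beta * (x - rf$mean) / rf$sd)
  bin <- findInterval(x, b$upper[-5], left.open = TRUE) + 1L
  oracle <- vapply(1:5, function(i)
    sum((rr * w)[bin == i]) / sum(w[bin == i]), 0)
  oracle <- oracle / sum(b$mass * oracle)
  expect_equal(b$rr, oracle, tolerance = 1e-6)
})

test_that("bins are normalised to population-mean RR 1", {
  for (n in c(2L, 5L, 21L)) for (beta in c(-0.3, 0.1013, 0.8)) {
    rf <- continuous_rf("x", 0, 1, beta)
    b <- discretise_rf(rf, n)
    expect_equal(sum(b$mass * b$rr), 1, tolerance = 1e-14)
    expect_equal(sum(b$mass), 1, tolerance = 1e-12)
  }
})

test_that("the observed bin carries the exact measured-value RR", {
  rf <- height_rf()
  b <- discretise_rf(rf, 5L)
  z <- attr(b, "normaliser")
  b1 <- add_observed_bin(b, rf$mean)
  expect_equal(b1$rr[6], 1 / z)
  expect_equal(b1$mass[6], 0)
  b2 <- add_observed_bin(b, rf$mean + rf$sd)
  expect_equal(b2$rr[6], exp(0.10130) / z)
  # masses untouched, still a distribution
  expect_equal(b2$mass[1:5], b$mass)
  expect_equal(sum(b2$mass), 1, tolerance = 1e-12)
  expect_error(add_observed_bin(b2, 150), "already")
  expect_error(add_observed_bin(b, 1e4), "support")
})

test_that("continuous RR variance has the stated closed form", {
  rf <- height_rf()
  expect_equal(rr_variance(rf), exp(0.10130^2) - 1)
  expect_equal(round(rr_variance(rf), 3), 0.010)
  # discrete variance against the dense-grid oracle
  b <- discretise_rf(rf, 5L)
  x <- seq(rf$mean - 8 * rf$sd, rf$mean + 8 * rf$sd, length.out = 1e6)
  w <- stats::dnorm(x, rf$mean, rf$sd)
  rr <- exp(rf$beta * (x - rf$mean) / rf$sd)
  bin <- findInterval(x, b$upper[-5], left.open = TRUE) + 1L
  rr_i <- vapply(1:5, function(i) sum((rr * w)[bin == i]) / sum(w[bin == i]), 0)
  p_i <- vapply(1:5, function(i) sum(w[bin == i]) / sum(w), 0)
  oracle_var <- sum(p_i * rr_i^2) / sum(p_i * rr_i)^2 - 1
  expect_equal(rr_variance(b), oracle_var, tolerance = 1e-5)
  # discretisation always loses variance
  expect_lt(rr_variance(b), rr_variance(rf))
})

test_that("discrete variance converges to the continuous value", {
  rf <- height_rf()
  v101 <- rr_variance(discretise_rf(rf, 101L))
  expect_lt(abs(v101 - (exp(rf$beta^2) - 1)), 1e-4)
})

test_that("the zero-mass observed bin leaves the baseline untouched", {
  rf <- height_rf()
  lam <- cohort_hazard(synth_incidence(), "bc", "F")
  b <- discretise_rf(rf, 5L)
  bo <- add_observed_bin(b, 175)
  d1 <- risk_profile_distribution(b$mass, matrix(b$rr, 5, 80))
  d2 <- risk_profile_distribution(bo$mass, matrix(bo$rr, 6, 80))
  l1 <- as.numeric(constrain_baseline(lam, d1))
  l2 <- as.numeric(constrain_baseline(lam, d2))
  expect_lt(max(abs(l1 - l2) / pmax(l1, 1e-300)), 1e-14)
})

test_that("observed-bin risk equals a brute-force fine discretisation", {
  rf <- height_rf()
  lam <- cohort_hazard(synth_incidence(), "bc", "F")
  xval <- 170
  risk_obs <- rf_lifetime_risk_functional(lam)(discretise_rf(rf, 5L), xval)
  # 1e5 equal-mass bins, closed-form per-bin RR for a lognormal RR
  nb <- 1e5L
  edges <- stats::qnorm(seq(0, 1, length.out = nb + 1L))
  edges[1] <- -8; edges[nb + 1L] <- 8
  mass <- stats::pnorm(edges[-1L]) - stats::pnorm(edges[-(nb + 1L)])
  beta <- rf$beta
  rrb <- exp(beta^2 / 2) *
    (stats::pnorm(edges[-1L] - beta) - stats::pnorm(edges[-(nb + 1L)] - beta)) /
    mass
  rrb <- rrb / sum(mass * rrb)
  lam0 <- constrain_baseline(lam, risk_profile_distribution(
    mass / sum(mass), matrix(rrb, nb, 80)))
  zx <- (xval - rf$mean) / rf$sd
  i <- findInterval(zx, edges, left.open = TRUE)
  risk_bf <- 1 - exp(-sum(lam0[21:80]) * rrb[i])
  expect_equal(risk_obs, risk_bf, tolerance = 1e-4)
})

test_that("a null effect selects the smallest candidate bin count", {
  rf0 <- continuous_rf("flat", 0, 1, 0)
  lam <- rep(2e-3, 80)
  sel <- choose_n_bins(rf0, rf_lifetime_risk_functional(lam))
  expect_equal(sel$n, 2L)
  expect_true(all(sel$errors <= 1e-12))
})

test_that("bin-count selection is definitionally consistent", {
  rf <- height_rf()
  lam <- rep(2e-3, 80)  # synthetic constant-incidence model
  sel <- choose_n_bins(rf, rf_lifetime_risk_functional(lam),
                       tolerance = 1e-4)
  ns <- as.integer(names(sel$errors))
  expect_lt(sel$errors[[as.character(sel$n)]], 1e-4)
  if (sel$n > 2L)
    expect_gte(sel$errors[[as.character(sel$n - 1L)]], 1e-4)
})
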