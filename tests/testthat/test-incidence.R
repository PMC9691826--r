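# cohort incidence construction and baseline-hazard constraining

test_that("constant calendar rates give a constant cohort hazard", {
  cal <- make_incidence("constant", base_rate = 100)
  coh <- build_cohort_incidence(cal, 1980:1989)
  expect_equal(cohort_hazard(coh, "bc", "F"), rep(100 / 1e5, 80L))
})

test_that("a single-year cohort follows its Lexis diagonal exactly", {
  years <- 1960:2019
  cal <- make_incidence("loglinear", base_rate = 50, period_slope = 0.01,
                        years = years)
  coh <- build_cohort_incidence(cal, 1970)
  got <- cohort_hazard(coh, "bc", "F") * 1e5
  want <- vapply(0:79, function(t) {
    y <- min(max(1970 + t, 1960), 2019)  # carry at the table edges
    50 * exp(0.01 * (y - 1960))
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("a decade cohort over a step change matches a hand-enumerated mean", {
  years <- 1980:2019
  df <- expand.grid(age = 0:79, year = years)
  df <- data.frame(country = "SYNTH", sex = "F", cancer = "bc",
                   age_lo = df$age, age_hi = df$age,
                   year_lo = df$year, year_hi = df$year,
                   rate_per_100k = ifelse(df$year < 2000, 50, 120))
  coh <- build_cohort_incidence(calendar_incidence(df), 1980:1989)
  got <- cohort_hazard(coh, "bc", "F") * 1e5
  # independent diagonal enumeration
  want <- vapply(0:79, function(t) {
    mean(vapply(1980:1989, function(y) {
      yy <- min(max(y + t, 1980), 2019)
      if (yy < 2000) 50 else 120
    }, 0))
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("periods outside the cohort diagonal cannot affect the result", {
  years <- 1990:2019
  cal <- make_incidence("loglinear", base_rate = 80, age_slope = 0.01,
                        years = years)
  base <- cohort_hazard(build_cohort_incidence(cal, 1990), "bc", "F")
  # prepend an absurd early period the 1990 cohort never reaches
  extra <- cal$table[cal$table$year_lo == 1990, ]
  extra$year_lo <- 1980; extra$year_hi <- 1989
  extra$rate_per_100k <- 99999
  cal2 <- calendar_incidence(rbind(extra, cal$table))
  expect_equal(cohort_hazard(build_cohort_incidence(cal2, 1990), "bc", "F"),
               base)
})

test_that("disjoint cohort and table raise an error", {
  cal <- make_incidence("constant", years = 1960:1990)
  expect_error(build_cohort_incidence(cal, 2000:2005), "overlap")
})

test_that("constraining with RR == 1 returns the population hazard", {
  lam <- rep(0.01, 80)
  dist <- risk_profile_distribution(c(0.4, 0.6), matrix(1, 2, 80))
  expect_equal(as.numeric(constrain_baseline(lam, dist)), lam)
})

test_that("two-profile constraining matches the closed form and the oracle", {
  lam <- rep(0.01, 80)
  rr <- matrix(rep(c(1, 2), 80), nrow = 2)
  dist <- risk_profile_distribution(c(0.5, 0.5), rr)
  lam0 <- as.numeric(constrain_baseline(lam, dist))
  expect_equal(lam0[1], 0.01 / 1.5)
  # independent survival-propagation oracle: the disease-free average
  # hazard must reproduce lambda_pop at every age
  S <- c(1, 1)
  for (t in 1:80) {
    avg <- sum(0.5 * S * rr[, t] * lam0[t]) / sum(0.5 * S)
    expect_equal(avg, lam[t], tolerance = 1e-12)
    S <- S * exp(-lam0[t] * rr[, t])
  }
  # high-RR profiles are progressively depleted, so lambda0 rises
  expect_true(all(diff(lam0) > 0))
})

test_that("zero-mass profiles do not perturb the baseline", {
  lam <- seq(1e-4, 5e-3, length.out = 80)
  rr <- matrix(exp(seq(-0.5, 0.5, length.out = 160)), nrow = 2)
  d1 <- risk_profile_distribution(c(0.3, 0.7), rr)
  d2 <- risk_profile_distribution(c(0.3, 0.7, 0), rbind(rr, 5))
  expect_equal(as.numeric(constrain_baseline(lam, d1)),
               as.numeric(constrain_baseline(lam, d2)))
})

test_that("merging profiles with identical RR leaves the baseline unchanged", {
  lam <- rep(0.005, 80)
  rr <- rbind(rep(1, 80), rep(2, 80), rep(2, 80))
  d3 <- risk_profile_distribution(c(0.5, 0.2, 0.3), rr)
  d2 <- risk_profile_distribution(c(0.5, 0.5), rr[1:2, ])
  expect_equal(as.numeric(constrain_baseline(lam, d3)),
               as.numeric(constrain_baseline(lam, d2)), tolerance = 1e-12)
})

test_that("shifting mass to high-RR profiles lowers the baseline", {
  lam <- rep(0.005, 80)
  rr <- rbind(rep(1, 80), rep(3, 80))
  l1 <- constrain_baseline(lam, risk_profile_distribution(c(0.7, 0.3), rr))
  l2 <- constrain_baseline(lam, risk_profile_distribution(c(0.5, 0.5), rr))
  expect_lt(l2[1], l1[1])
})

test_that("expected_population_hazard inverts the constraint", {
  set.seed(42)
  lam <- runif(80, 1e-5, 8e-3)
  rr <- matrix(exp(stats::rnorm(5 * 80, sd = 0.7)), nrow = 5)
  mass <- as.numeric(stats::rexp(5)); mass <- mass / sum(mass)
  dist <- risk_profile_distribution(mass, rr)
  lam0 <- constrain_baseline(lam, dist)
  expect_equal(expected_population_hazard(lam0, dist), lam,
               tolerance = 1e-10)
  # and with RR == 1 it returns the baseline itself
  d1 <- risk_profile_distribution(1, matrix(1, 1, 80))
  expect_equal(expected_population_hazard(lam, d1), lam)
})

test_that("profile distributions validate mass and positivity", {
  expect_error(risk_profile_distribution(c(0.5, 0.4), matrix(1, 2, 80)),
               "sum to 1")
  expect_error(risk_profile_distribution(c(0.5, 0.5),
                                         matrix(c(-1, 1), 2, 80)),
               "positive")
})

test_that("cohort incidence TSVs round-trip through read/write", {
  inc <- synth_incidence()
  path <- tempfile(fileext = ".tsv")
  write_cohort_incidence(inc, path)
  expect_equal(read_cohort_incidence(path)$table$rate_per_100k,
               inc$table$rate_per_100k)
})
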