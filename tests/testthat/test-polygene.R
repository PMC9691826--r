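# polygene discretisation, transmission, variance adjustment and PRS

test_that("three levels reproduce the standardised Binomial(2, 1/2)", {
  d <- discretise_polygene(3L)
  expect_equal(d$masses, c(0.25, 0.5, 0.25))
  expect_equal(d$values, c(-sqrt(2), 0, sqrt(2)))
})

test_that("every discretisation has exact unit moments", {
  for (n in c(3L, 5L, 7L, 9L, 15L)) {
    d <- discretise_polygene(n)
    expect_equal(sum(d$masses), 1, tolerance = 1e-15)
    expect_equal(sum(d$masses * d$values), 0, tolerance = 1e-15)
    expect_equal(sum(d$masses * d$values^2), 1, tolerance = 1e-12)
  }
  expect_error(discretise_polygene(4L), "odd")
  expect_error(discretise_polygene(1L), "odd")
})

test_that("seven levels equal an exhaustive sum over six biallelic loci", {
  d <- discretise_polygene(7L)
  alleles <- as.matrix(expand.grid(rep(list(0:1), 6)))
  dose <- rowSums(alleles)
  mass <- as.numeric(table(factor(dose, levels = 0:6))) / 64
  vals <- (0:6 - 3) / sqrt(6 / 4)
  expect_equal(d$masses, mass)
  expect_equal(d$values, vals)
  expect_equal(sum(mass * vals^3), sum(d$masses * d$values^3))
})

test_that("population-mean polygenic RR is exactly 1 after normalisation", {
  pg <- polygene_model(sd = seq(0.5, 1.5, length.out = 80), n_levels = 7L)
  rrm <- polygene_rr_matrix(pg)
  expect_equal(as.numeric(colSums(rrm * pg$masses)), rep(1, 80),
               tolerance = 1e-14)
  # at moderate SD the raw lognormal normaliser is already close
  for (n in c(7L, 9L, 15L)) {
    d <- discretise_polygene(n)
    for (s in c(0.1, 0.3, 0.5)) {
      approx_mean <- sum(d$masses * exp(s * d$values - s^2 / 2))
      expect_lt(abs(approx_mean - 1), 1e-3)
    }
  }
})

test_that("hypergeometric transmission is stationary with midparent mean", {
  for (L in c(3L, 7L)) {
    K <- polygene_transmission(L)
    mass <- stats::dbinom(0:(L - 1L), L - 1L, 0.5)
    child <- numeric(L)
    for (f in 1:L) for (m in 1:L)
      child <- child + mass[f] * mass[m] * K[, f, m]
    expect_equal(child, mass, tolerance = 1e-12)
    for (f in 1:L) for (m in 1:L) {
      expect_equal(sum(K[, f, m]), 1, tolerance = 1e-12)
      expect_equal(sum((0:(L - 1L)) * K[, f, m]), (f + m - 2) / 2,
                   tolerance = 1e-12)
    }
  }
})

test_that("gene variance contribution matches the closed form", {
  w <- rep(1 / 80, 80)
  g_null <- gene_params("NULLG", 0.001, 0.9)  # no associations: RR == 1
  expect_equal(gene_log_rr_variance(g_null, "bc", w)$v_bar, 0)
  # carrier probability 0.001 via q(2-q) = 0.001
  q <- 1 - sqrt(1 - 0.001)
  apr <- age_piecewise_rr(data.frame(age_lo = 0, age_hi = 79,
                                     form = "constant", c = 2,
                                     u = NA, v = NA))
  g2 <- gene_params("G2", q, 0.9, rr = list(bc = apr))
  v <- gene_log_rr_variance(g2, "bc", w)
  expect_equal(v$v_bar, 0.001 * 0.999 * log(2)^2, tolerance = 1e-10)
  # weighting: concentrating the weights where RR is constant changes nothing
  w2 <- c(rep(0, 40), rep(1 / 40, 40))
  expect_equal(gene_log_rr_variance(g2, "bc", w2)$v_bar, v$v_bar)
})

test_that("gene variance agrees with a Monte-Carlo indicator variance", {
  set.seed(7)
  p <- 0.05
  lnrr <- log(2)
  x <- ifelse(runif(2e4) < p, lnrr, 0)
  se <- stats::sd(x)^2 * sqrt(2 / (2e4 - 1))  # approx SE of a variance
  expect_lt(abs(stats::var(x) - p * (1 - p) * lnrr^2), 3 * se + 1e-5)
})

test_that("polygenic variance is conserved exactly under adjustment", {
  w <- incidence_weights(synth_incidence(), "bc", "F")
  genes <- test_config()$genes$bc[c("BARD1", "RAD51C", "RAD51D")]
  contr <- lapply(genes, gene_log_rr_variance, cancer = "bc", weights = w)
  sd_old <- rep(1, 80)
  sd_new <- adjust_polygenic_sd(sd_old, contr)
  vtot <- Reduce(`+`, lapply(contr, `[[`, "v_by_age"))
  expect_equal(sd_new^2 + vtot, sd_old^2, tolerance = 1e-15)
  expect_true(all(sd_new < sd_old))
  # empty set and null genes leave sigma unchanged
  expect_identical(adjust_polygenic_sd(sd_old), sd_old)
  g_null <- gene_params("NULLG", 0.001, 0.9)
  expect_identical(adjust_polygenic_sd(
    sd_old, list(gene_log_rr_variance(g_null, "bc", w))), sd_old)
})

test_that("a variance deficit is refused", {
  apr <- age_piecewise_rr(data.frame(age_lo = 0, age_hi = 79,
                                     form = "constant", c = 1000,
                                     u = NA, v = NA))
  g <- gene_params("BIG", 0.009, 0.9, rr = list(bc = apr))
  contr <- list(gene_log_rr_variance(g, "bc", rep(1 / 80, 80)))
  expect_error(adjust_polygenic_sd(0.3, contr), "deficit")
})

test_that("PRS conditioning shifts and rescales the polygene", {
  pg0 <- polygene_model(sd = 1.2, n_levels = 7L, alpha2 = 0)
  c0 <- condition_on_prs(pg0, z = 2.5)
  expect_equal(c0$values, 1.2 * pg0$values)  # unchanged for any z
  pg1 <- polygene_model(sd = 1.2, n_levels = 7L, alpha2 = 1)
  c1 <- condition_on_prs(pg1, z = 0.7)
  expect_equal(c1$values, rep(0.7 * 1.2, 7L))  # point mass at z * sigma
  pg <- polygene_model(sd = 1.2, n_levels = 7L, alpha2 = 0.20)
  cz <- condition_on_prs(pg, z = 0)
  expect_equal(cz$mean, 0)
  expect_equal(cz$sd, sqrt(0.8) * 1.2)
  expect_equal(sum(cz$masses * cz$values), 0, tolerance = 1e-12)
  expect_error(polygene_model(alpha2 = 1.2), "alpha2")
})

test_that("mixing PRS-conditioned polygenes over z recovers the prior", {
  set.seed(11)
  pg <- polygene_model(sd = 1, n_levels = 7L, alpha2 = 0.20)
  n <- 4000L
  zs <- stats::rnorm(n)
  means <- vapply(zs, function(z) {
    cz <- condition_on_prs(pg, z)
    sum(cz$masses * cz$values)
  }, 0)
  m2 <- vapply(zs, function(z) {
    cz <- condition_on_prs(pg, z)
    sum(cz$masses * cz$values^2)
  }, 0)
  se_mean <- stats::sd(means) / sqrt(n)
  se_var <- stats::sd(m2) / sqrt(n)
  expect_lt(abs(mean(means) - 0), 3 * se_mean)
  expect_lt(abs(mean(m2) - 1), 3 * se_var + 1e-3)
})
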