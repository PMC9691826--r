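# pedigree I/O and validation, observation likelihoods, peeling

trio_df <- function() {
  data.frame(id = c("c", "f", "m"), father = c("f", "0", "0"),
             mother = c("m", "0", "0"), sex = c("F", "M", "F"),
             birth_year = c(1985, 1955, 1958),
             censor_age = c(35, 65, 62),
             bc_age = c(0, 0, 50), target = c(1L, 0L, 0L),
             stringsAsFactors = FALSE)
}

test_that("pedigree files round-trip losslessly", {
  p1 <- singleton(height = 170.5, prs_z = 0.3, BARD1_test = "P")
  f <- tempfile(fileext = ".ped")
  write_pedigree(p1, f)
  expect_equal(as.data.frame(read_pedigree(f)), as.data.frame(p1),
               ignore_attr = TRUE)
  ped <- pedigree(trio_df())
  write_pedigree(ped, f)
  got <- read_pedigree(f)
  expect_equal(as.data.frame(got), as.data.frame(ped), ignore_attr = TRUE)
  expect_equal(got$bc_age[got$id == "m"], 50)
  expect_error(read_pedigree(tempfile()), "cannot open|No such")
  # version tag is mandatory
  writeLines(c("id\tfather", "1\t0"), f)
  expect_error(read_pedigree(f), "version tag")
})

test_that("structural defects are rejected with row-level messages", {
  d <- trio_df()
  d$birth_year[1] <- 1940  # child older than parents
  expect_error(pedigree(d), "born before")
  d <- trio_df(); d$id[2] <- "c"
  expect_error(pedigree(d), "duplicate")
  d <- trio_df(); d$mother[1] <- "0"
  expect_error(pedigree(d), "two parents or none")
  d <- trio_df(); d$father[1] <- "nobody"
  expect_error(pedigree(d), "unknown father")
  d <- trio_df(); d$sex[2] <- "F"
  expect_error(pedigree(d), "not male")
  d <- rbind(trio_df(),
             data.frame(id = "x", father = "0", mother = "0", sex = "F",
                        birth_year = 1990, censor_age = 30, bc_age = 0,
                        target = 0L))
  expect_error(pedigree(d), "connected")
  d <- trio_df(); d$eoc_age <- c(0, 30, 0)  # ovarian cancer in a male
  expect_error(pedigree(d), "incompatible with sex")
  d <- trio_df(); d$bc_age[3] <- 70  # diagnosis after censoring
  expect_error(pedigree(d), "after censor")
  d <- trio_df(); d$pathology <- c(4L, 0L, 0L)  # pathology without BC
  expect_error(pedigree(d), "pathology without")
})

test_that("test_likelihood implements sensitivity with specificity 1", {
  expect_equal(test_likelihood("N", TRUE, 1), 0)
  expect_equal(test_likelihood("N", TRUE, 0.78), 0.22)  # RAD51C SS
  expect_equal(test_likelihood("P", TRUE, 0.78), 0.78)
  expect_equal(test_likelihood("P", FALSE, 0.9), 0)
  expect_equal(test_likelihood("N", FALSE, 0.9), 1)
})

test_that("phenotype likelihoods match closed forms", {
  m <- tiny_model()
  newborn <- as.list(singleton(censor = 0)[1, ])
  expect_equal(phenotype_likelihood(newborn, "none", 2L, m), 1)
  # affected non-carrier at age a: S(a) * lambda(a) with the polygenic RR
  a <- 45L
  aff <- as.list(singleton(censor = a, bc_age = a)[1, ])
  d <- discretise_polygene(3L)
  r_mid <- exp(1 * d$values[2]) / sum(d$masses * exp(1 * d$values))
  lam0 <- as.numeric(m$baseline$bc)
  want <- exp(-sum(lam0[1:a] * r_mid)) * lam0[a + 1L] * r_mid *
    exp(-sum(m$baseline$eoc[1:a]) - sum(m$baseline$pancreas_F[1:a]))
  expect_equal(phenotype_likelihood(aff, "none", 2L, m), want,
               tolerance = 1e-12)
})

test_that("tumour pathology multiplies in the gene-specific category prob", {
  m <- tiny_model()
  base <- as.list(singleton(censor = 40, bc_age = 40)[1, ])
  tn <- base; tn$pathology <- 4L
  dist <- test_config()$pathology$BARD1
  p <- pathology_category_prob(dist, "TN", 40)
  expect_equal(phenotype_likelihood(tn, "BARD1", 1L, m) /
                 phenotype_likelihood(base, "BARD1", 1L, m), p,
               tolerance = 1e-12)
})

test_that("peeling equals enumeration and ignores labelling", {
  m <- tiny_model()
  ped <- pedigree(trio_df())
  pl <- peel_likelihood(ped, m)
  expect_equal(pl, enumerate_pedigree_likelihood(ped, m),
               tolerance = 1e-12)
  # relabel ids and shuffle rows
  d <- trio_df()
  d$id <- c("zz", "aa", "bb"); d$father[1] <- "aa"; d$mother[1] <- "bb"
  d <- d[c(2, 3, 1), ]
  expect_equal(peel_likelihood(pedigree(d), m), pl, tolerance = 1e-12)
})

test_that("a single untested unaffected newborn founder has likelihood 1", {
  m <- tiny_model()
  expect_equal(peel_likelihood(singleton(censor = 0), m), 1,
               tolerance = 1e-12)
  expect_equal(carrier_probabilities(singleton(censor = 0), m),
               setNames(c(m$prior_major), c("noncarrier", m$gene_names)))
})

test_that("posteriors sum to one and ignore uninformative relatives", {
  m <- tiny_model()
  ped <- pedigree(trio_df())
  post <- state_posterior(ped, m)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # attach an uninformative spouse and newborn child to the target
  d <- trio_df()
  d2 <- rbind(d, data.frame(id = c("s", "k"), father = c("0", "s"),
                            mother = c("0", "c"), sex = c("M", "F"),
                            birth_year = c(1984, 2019),
                            censor_age = c(0, 0), bc_age = 0,
                            target = 0L))
  expect_equal(state_posterior(pedigree(d2), m), post, tolerance = 1e-12)
})

test_that("negative and positive tests update carriage by Bayes' rule", {
  m <- bard1_model()  # single-gene model: closed forms are exact
  p <- carrier_prob(test_config()$genes$bc$BARD1)
  ss <- 0.89
  neg <- singleton(censor = 0, BARD1_test = "N")
  want <- p * (1 - ss) / (p * (1 - ss) + (1 - p))
  expect_equal(carrier_probabilities(neg, m)[["BARD1"]], want,
               tolerance = 1e-12)
  pos <- singleton(censor = 0, BARD1_test = "P")
  expect_equal(carrier_probabilities(pos, m)[["BARD1"]], 1)
  # sensitivity 1: a negative test excludes carriage
  cfg <- test_config()
  cfg$genes$bc$BARD1$sensitivity <- 1
  m1 <- risk_model(cfg, synth_incidence(), "bc", genes = "BARD1",
                   n_polygene_levels = 3L, use_risk_factors = FALSE)
  expect_equal(carrier_probabilities(neg, m1)[["BARD1"]], 0)
  # contradictory data: two confirmed PVs under single-carrier collapse
  m2 <- tiny_model()
  both <- singleton(censor = 0, BRCA1_test = "P", BARD1_test = "P")
  expect_error(carrier_probabilities(both, m2), "inconsistent")
})

test_that("a TN tumour favours BARD1 more than an ER-positive tumour", {
  m <- default_model("bc")
  tn <- singleton(censor = 40, bc_age = 40, pathology = 4L)
  erpos <- singleton(censor = 40, bc_age = 40, pathology = 1L)
  cp_tn <- carrier_probabilities(tn, m)
  cp_er <- carrier_probabilities(erpos, m)
  expect_gt(cp_tn[["BARD1"]], cp_er[["BARD1"]])
  expect_gt(cp_tn[["RAD51C"]], cp_er[["RAD51C"]])
  expect_equal(sum(cp_tn), 1, tolerance = 1e-12)
})

test_that("peeling is exact on pedigrees with marry-ins and grandchildren", {
  m <- tiny_model()
  for (seed in c(21L, 22L)) {
    ped <- make_pedigree(m, size = 6L, seed = seed)
    expect_equal(peel_likelihood(ped, m),
                 enumerate_pedigree_likelihood(ped, m),
                 tolerance = 1e-9)
  }
})
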