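# Deterministic synthetic-data generators: calendar incidence tables,
# tumour-pathology tables, random pedigrees simulated from the model, and
# a single-gene simulation/recovery pair. Everything here is synthetic and
# labelled as such; nothing imitates a real registry.

#' Synthetic calendar-period incidence table
#'
#' Rates follow a stated deterministic model -- constant, or log-linear in
#' age and calendar period -- on a single-year age by period grid covering
#' ages 0--79 and at least 30 calendar years.
#'
#' @param rate_model \code{"constant"} or \code{"loglinear"}.
#' @param base_rate rate per 100,000 at the reference cell.
#' @param age_slope,period_slope log-linear coefficients (per year of age /
#'   per calendar year since the first year).
#' @param years calendar years covered (>= 30).
#' @param country,sex,cancer stratum labels.
#' @return a \code{\link{calendar_incidence}}.
#' @export
make_incidence <- function(rate_model = c("constant", "loglinear"),
                           base_rate = 100, age_slope = 0, period_slope = 0,
                           years = 1990:2019, country = "SYNTH", sex = "F",
                           cancer = "bc") {
  rate_model <- match.arg(rate_model)
  stopifnot(base_rate >= 0, length(years) >= 30L)
  grid <- expand.grid(age = 0:79, year = years, KEEP.OUT.ATTRS = FALSE)
  rate <- if (rate_model == "constant") rep(base_rate, nrow(grid))
          else base_rate * exp(age_slope * grid$age +
                               period_slope * (grid$year - years[1L]))
  calendar_incidence(data.frame(
    country = country, sex = sex, cancer = cancer,
    age_lo = grid$age, age_hi = grid$age,
    year_lo = grid$year, year_hi = grid$year, rate_per_100k = rate))
}

# logistic ER-negative curve parameters mirroring the shipped synthetic
# pathology table: BARD1/RAD51C/RAD51D mostly ER-negative and decreasing
# with age, CHEK2/ATM mostly ER-positive with the ER+ share increasing
# with age, population constant
SYNTH_PATHOLOGY_PARAMS <- data.frame(
  gene = c("population", "BRCA1", "BRCA2", "PALB2", "CHEK2", "ATM",
           "BARD1", "RAD51C", "RAD51D"),
  p50  = c(0.20, 0.75, 0.25, 0.45, 0.15, 0.20, 0.78, 0.72, 0.70),
  b    = c(0, -0.020, -0.010, -0.020, -0.015, -0.015, -0.030, -0.030, -0.030),
  tn   = c(0.33, 0.70, 0.40, 0.60, 0.25, 0.35, 0.75, 0.72, 0.70),
  stringsAsFactors = FALSE)

#' Synthetic tumour-pathology distributions
#'
#' Age-dependent ER-negative proportions as monotone logistic curves in
#' age, with gene-specific directions, and constant TN-given-ER-negative
#' proportions. Matches the shipped \code{synthetic_pathology.tsv}.
#'
#' @param genes which tables to generate (default all, including
#'   \code{"population"}).
#' @param ages tabulated onset ages.
#' @return named list of \code{\link{pathology_distribution}}.
#' @export
make_pathology_tables <- function(genes = SYNTH_PATHOLOGY_PARAMS$gene,
                                  ages = c(seq(20, 75, by = 5), 79)) {
  par <- SYNTH_PATHOLOGY_PARAMS[SYNTH_PATHOLOGY_PARAMS$gene %in% genes, ]
  if (nrow(par) == 0L) stop("make_pathology_tables: unknown genes")
  out <- lapply(seq_len(nrow(par)), function(i) {
    p <- stats::plogis(stats::qlogis(par$p50[i]) + par$b[i] * (ages - 50))
    pathology_distribution(par$gene[i], ages, p, rep(par$tn[i], length(ages)))
  })
  stats::setNames(out, par$gene)
}

# simulate age at onset (0 = none) under per-age hazard lam, censored at a
sim_onset <- function(lam, a) {
  if (a < 1) return(0L)
  for (t in seq_len(min(a, 80L))) {
    if (stats::runif(1L) < 1 - exp(-lam[t])) return(max(t - 1L, 1L))
  }
  0L
}

#' Random pedigree simulated from the model
#'
#' Generates a structurally valid random pedigree (founder couples,
#' marry-ins, children) and simulates every individual's data from the
#' model itself: founder genotype states from the population priors,
#' children by Mendelian/polygenic transmission, cancer onsets from the
#' genotype-specific hazards, tumour pathology from the carried gene's
#' distribution, test results through the screening sensitivities and PRS
#' values from the polygene. Observations are thinned at the given
#' missingness rates. The same seed reproduces the same pedigree exactly.
#'
#' @param model a \code{\link{risk_model}}.
#' @param size number of individuals (>= 1; a size of 2 is promoted to 3
#'   since every non-founder needs both parents present).
#' @param seed RNG seed.
#' @param p_tested per-gene probability an individual's test is recorded.
#' @param p_pathology probability ER status is recorded for a breast
#'   cancer; given ER-negative, TN status is recorded with probability 0.7.
#' @param p_prs,p_height observation probabilities for PRS and height.
#' @param current_year censoring reference year.
#' @return a \code{\link{pedigree}} with the simulated true genotype
#'   states in \code{attr(, "true_states")}.
#' @export
make_pedigree <- function(model, size = 4L, seed = 1L, p_tested = 0.5,
                          p_pathology = 0.6, p_prs = 0.3, p_height = 0.4,
                          current_year = 2020L) {
  if (size < 1L) stop("make_pedigree: size must be >= 1")
  set.seed(seed)
  n_target <- if (size == 2L) 3L else as.integer(size)

  # structure: id, father, mother, sex, birth_year (parents precede children)
  ppl <- data.frame(id = "1", father = "0", mother = "0",
                    sex = sample(c("F", "M"), 1L),
                    birth_year = sample(1930:1950, 1L),
                    stringsAsFactors = FALSE)
  nid <- 1L
  new_id <- function() { nid <<- nid + 1L; as.character(nid) }
  spouses <- character(0)  # ids that already have a spouse
  couples <- list()        # list of c(father, mother)
  while (nrow(ppl) < n_target) {
    room <- n_target - nrow(ppl)
    spouseless <- setdiff(ppl$id, spouses)
    if (room >= 2L && (length(couples) == 0L || stats::runif(1L) < 0.5) &&
        length(spouseless) > 0L) {
      p <- spouseless[sample.int(length(spouseless), 1L)]
      pi <- match(p, ppl$id)
      s <- new_id()
      srow <- data.frame(id = s, father = "0", mother = "0",
                         sex = if (ppl$sex[pi] == "F") "M" else "F",
                         birth_year = ppl$birth_year[pi] + sample(-5:5, 1L),
                         stringsAsFactors = FALSE)
      fa <- if (srow$sex == "M") s else p
      mo <- if (srow$sex == "M") p else s
      ch <- new_id()
      crow <- data.frame(id = ch, father = fa, mother = mo,
                         sex = sample(c("F", "M"), 1L),
                         birth_year = max(ppl$birth_year[pi],
                                          srow$birth_year) +
                           sample(20:32, 1L),
                         stringsAsFactors = FALSE)
      ppl <- rbind(ppl, srow, crow)
      spouses <- c(spouses, p, s)
      couples[[length(couples) + 1L]] <- c(fa, mo)
    } else if (length(couples) > 0L) {
      cp <- couples[[sample.int(length(couples), 1L)]]
      by <- max(ppl$birth_year[match(cp, ppl$id)]) + sample(20:32, 1L)
      ppl <- rbind(ppl, data.frame(id = new_id(), father = cp[1L],
                                   mother = cp[2L],
                                   sex = sample(c("F", "M"), 1L),
                                   birth_year = by,
                                   stringsAsFactors = FALSE))
    } else {
      break  # size 2 guard; cannot attach a lone spouse
    }
  }
  ppl$censor_age <- pmax(pmin(current_year - ppl$birth_year, 80L), 0L)

  # genotype states, parents before children by construction order
  L <- model$pg$n_levels
  st_g <- integer(nrow(ppl)); st_l <- integer(nrow(ppl))
  prior <- model$prior_major
  for (i in seq_len(nrow(ppl))) {
    if (ppl$father[i] == "0") {
      st_g[i] <- sample(0:model$K, 1L, prob = prior)
      st_l[i] <- sample.int(L, 1L, prob = model$pg$masses)
    } else {
      fi <- match(ppl$father[i], ppl$id); mi <- match(ppl$mother[i], ppl$id)
      st_g[i] <- sample(0:model$K, 1L,
                        prob = model$major_kernel[, st_g[fi] + 1L,
                                                  st_g[mi] + 1L])
      st_l[i] <- sample.int(L, 1L,
                            prob = model$pg_kernel[, st_l[fi], st_l[mi]])
    }
  }
  states <- st_g * L + st_l

  # phenotypes simulated from the genotype-specific hazards
  for (col in c("bc_age", "eoc_age", "prostate_age", "pancreas_age"))
    ppl[[col]] <- 0L
  ppl$pathology <- 0L
  for (i in seq_len(nrow(ppl))) {
    dxcols <- individual_cancers(ppl$sex[i])
    for (cn in names(dxcols)) {
      key <- hazard_key(cn, ppl$sex[i])
      lam0 <- model$baseline[[key]]
      if (is.null(lam0)) next
      lam <- lam0 * model$state_rr[[cn]][states[i], ]
      dx <- sim_onset(lam, ppl$censor_age[i])
      if (dx > 0L) ppl[[dxcols[[cn]]]][i] <- dx
    }
    if (ppl$sex[i] == "F" && ppl$bc_age[i] > 0L &&
        stats::runif(1L) < p_pathology) {
      g <- if (st_g[i] == 0L) "population" else model$gene_names[st_g[i]]
      dist <- model$pathology[[g]]
      if (is.null(dist)) dist <- model$pathology$population
      p <- path_lookup(dist, ppl$bc_age[i])
      if (stats::runif(1L) < p[["er"]]) {  # ER-negative
        ppl$pathology[i] <- if (stats::runif(1L) > 0.7) 2L
          else if (stats::runif(1L) < p[["tn"]]) 4L else 3L
      } else ppl$pathology[i] <- 1L
    }
  }

  for (g in seq_along(model$gene_names)) {
    col <- paste0(model$gene_names[g], "_test")
    res <- rep("0", nrow(ppl))
    tested <- stats::runif(nrow(ppl)) < p_tested
    carrier <- st_g == g
    pos <- carrier & (stats::runif(nrow(ppl)) < model$sens[g])
    res[tested & pos] <- "P"
    res[tested & !pos] <- "N"
    ppl[[col]] <- res
  }

  al <- sqrt(model$pg$alpha2)
  vz <- model$pg$values[st_l]
  ppl$prs_z <- ifelse(stats::runif(nrow(ppl)) < p_prs,
                      stats::rnorm(nrow(ppl), al * vz,
                                   sqrt(1 - model$pg$alpha2)),
                      NA_real_)
  hb <- model$rfs$height
  if (!is.null(hb)) {
    rf <- attr(hb, "rf")
    ppl$height <- ifelse(stats::runif(nrow(ppl)) < p_height,
                         round(stats::rnorm(nrow(ppl), rf$mean, rf$sd), 1),
                         NA_real_)
  }
  ppl$target <- 0L
  ppl$target[sample.int(nrow(ppl), 1L)] <- 1L
  ped <- pedigree(ppl)
  attr(ped, "true_states") <- states
  ped
}

#' Simulate a single-gene cohort of unrelated individuals
#'
#' Founders only: carrier status from the Hardy-Weinberg carrier
#' probability of allele frequency \code{q}, and age at onset from the
#' per-year hazard \code{lambda0} multiplied by \code{rr} for carriers.
#' Everyone is followed to age 80. Used for simulation-based parameter
#' recovery.
#'
#' @param q allele frequency (carrier probability \code{q(2-q)}).
#' @param rr carrier hazard ratio (constant over age).
#' @param lambda0 length-80 baseline hazard (per person-year).
#' @param n cohort size.
#' @param seed RNG seed.
#' @return data.frame with \code{carrier}, \code{affected}, \code{age}
#'   (onset age if affected, else 80).
#' @export
simulate_gene_cohort <- function(q, rr, lambda0, n, seed = 1L) {
  stopifnot(length(lambda0) == 80L, n >= 1L)
  set.seed(seed)
  carrier <- stats::runif(n) < carrier_prob(q)
  age <- rep(80L, n); affected <- rep(FALSE, n)
  alive <- rep(TRUE, n)
  for (t in 1:80) {
    p <- 1 - exp(-lambda0[t] * ifelse(carrier, rr, 1))
    ev <- alive & (stats::runif(n) < p)
    age[ev] <- t - 1L
    affected[ev] <- TRUE
    alive <- alive & !ev
  }
  data.frame(carrier = carrier, affected = affected, age = age)
}

#' Grid-search maximum likelihood for a single-gene hazard ratio
#'
#' Discrete-time likelihood matching \code{\link{simulate_gene_cohort}}:
#' each person contributes survival
#' \eqn{\prod_{t < age} e^{-\lambda_0(t) r}} and, if affected,
#' \eqn{1 - e^{-\lambda_0(age) r}}, with r the candidate hazard ratio for
#' carriers and 1 otherwise.
#'
#' @param cohort data.frame from \code{\link{simulate_gene_cohort}}.
#' @param lambda0 the known baseline hazard used in the simulation.
#' @param grid candidate hazard ratios.
#' @return list with \code{rr_hat}, \code{grid}, \code{loglik}.
#' @export
fit_single_gene_rr <- function(cohort, lambda0,
                               grid = seq(1, 4, by = 0.005)) {
  stopifnot(length(lambda0) == 80L)
  H <- c(0, cumsum(lambda0))         # H[t+1] = sum_{u<t} lambda0(u)
  hsurv <- H[cohort$age + 1L]
  lam_ev <- ifelse(cohort$affected, lambda0[pmin(cohort$age, 79L) + 1L], 0)
  ll <- vapply(grid, function(r) {
    ri <- ifelse(cohort$carrier, r, 1)
    sum(-ri * hsurv) +
      sum(log(1 - exp(-lam_ev[cohort$affected] *
                        ri[cohort$affected])))
  }, 0)
  list(rr_hat = grid[which.max(ll)], grid = grid, loglik = ll)
}
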