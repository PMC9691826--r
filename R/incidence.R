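# Population incidence: birth-cohort rates from calendar-period tables, and
# baseline hazards constrained so the model averages back to the population
# rates at every age.

#' Calendar-period incidence table
#'
#' Population incidence rates per 100,000 person-years on an age-group by
#' calendar-period grid, as published by cancer registries.
#'
#' @param df data.frame with columns \code{country}, \code{sex},
#'   \code{cancer}, \code{age_lo}, \code{age_hi}, \code{year_lo},
#'   \code{year_hi}, \code{rate_per_100k}. Age groups must tile 0--79 and
#'   periods must be contiguous within each (country, sex, cancer) stratum.
#' @export
calendar_incidence <- function(df) {
  need <- c("country", "sex", "cancer", "age_lo", "age_hi", "year_lo",
            "year_hi", "rate_per_100k")
  if (!all(need %in% names(df)))
    stop(sprintf("calendar_incidence: missing columns %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (any(df$rate_per_100k < 0)) stop("calendar_incidence: negative rates")
  strata <- unique(df[, c("country", "sex", "cancer")])
  for (i in seq_len(nrow(strata))) {
    s <- df[df$country == strata$country[i] & df$sex == strata$sex[i] &
            df$cancer == strata$cancer[i], , drop = FALSE]
    ag <- unique(s[, c("age_lo", "age_hi")])
    ag <- ag[order(ag$age_lo), , drop = FALSE]
    cov <- unlist(mapply(seq, ag$age_lo, ag$age_hi, SIMPLIFY = FALSE))
    if (anyDuplicated(cov) || !setequal(cov, 0:79))
      stop(sprintf("calendar_incidence: age groups for %s/%s/%s do not tile 0-79",
                   strata$country[i], strata$sex[i], strata$cancer[i]))
    pr <- unique(s[, c("year_lo", "year_hi")])
    pr <- pr[order(pr$year_lo), , drop = FALSE]
    if (nrow(pr) > 1L && any(pr$year_lo[-1L] != pr$year_hi[-nrow(pr)] + 1L))
      stop("calendar_incidence: calendar periods must be contiguous")
  }
  structure(list(table = df), class = "calendar_incidence")
}

#' Build birth-cohort incidence from calendar-period rates
#'
#' Follows each birth year's diagonal through the age-by-period Lexis grid
#' and averages the calendar rates at (age t, year y + t) over all birth
#' years y in the cohort. Cells beyond the observed calendar range borrow
#' the nearest observed period (carry-forward past the last period,
#' carry-back before the first). Averaging over the cohort's years smooths
#' year-on-year fluctuation in sparse registries.
#'
#' @param cal a \code{\link{calendar_incidence}} table.
#' @param birth_cohort integer vector of birth years (e.g. \code{1980:1989})
#'   or a single year.
#' @param label cohort label for the output (default: year span).
#' @return A \code{cohort_incidence} object: data.frame with columns
#'   \code{cohort}, \code{sex}, \code{cancer}, \code{age} (0--79) and
#'   \code{rate_per_100k}, one stratum per (sex, cancer) in \code{cal}.
#' @export
build_cohort_incidence <- function(cal, birth_cohort, label = NULL) {
  stopifnot(inherits(cal, "calendar_incidence"))
  years <- min(birth_cohort):max(birth_cohort)
  if (is.null(label))
    label <- if (length(years) == 1L) as.character(years) else
      sprintf("%d-%d", min(years), max(years))
  df <- cal$table
  if (min(years) > max(df$year_hi) || max(years) + 79L < min(df$year_lo))
    stop("build_cohort_incidence: cohort has no overlap with the table")
  out <- list()
  strata <- unique(df[, c("sex", "cancer")])
  for (i in seq_len(nrow(strata))) {
    s <- df[df$sex == strata$sex[i] & df$cancer == strata$cancer[i], ,
            drop = FALSE]
    rate <- vapply(0:79, function(t) {
      yr <- pmin(pmax(years + t, min(s$year_lo)), max(s$year_hi))
      cell <- vapply(yr, function(y) {
        hit <- s$age_lo <= t & s$age_hi >= t & s$year_lo <= y & s$year_hi >= y
        s$rate_per_100k[which(hit)[1L]]
      }, 0)
      mean(cell)
    }, 0)
    out[[i]] <- data.frame(cohort = label, sex = strata$sex[i],
                           cancer = strata$cancer[i], age = 0:79,
                           rate_per_100k = rate)
  }
  structure(list(table = do.call(rbind, out)), class = "cohort_incidence")
}

#' Read / construct a cohort incidence table
#'
#' @param df data.frame with columns \code{cohort}, \code{sex},
#'   \code{cancer}, \code{age}, \code{rate_per_100k}, complete over ages
#'   0--79 in each stratum.
#' @export
cohort_incidence <- function(df) {
  need <- c("cohort", "sex", "cancer", "age", "rate_per_100k")
  if (!all(need %in% names(df)))
    stop(sprintf("cohort_incidence: missing columns %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (any(df$rate_per_100k < 0)) stop("cohort_incidence: negative rates")
  strata <- unique(df[, c("sex", "cancer")])
  for (i in seq_len(nrow(strata))) {
    s <- df[df$sex == strata$sex[i] & df$cancer == strata$cancer[i], ]
    if (!setequal(s$age, 0:79) || nrow(s) != 80L)
      stop(sprintf("cohort_incidence: stratum %s/%s must cover ages 0-79 once",
                   strata$sex[i], strata$cancer[i]))
  }
  structure(list(table = df), class = "cohort_incidence")
}

#' Read a cohort incidence TSV
#' @param path TSV with the \code{\link{cohort_incidence}} columns.
#' @export
read_cohort_incidence <- function(path) {
  cohort_incidence(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
}

#' Write a cohort incidence TSV
#' @param inc a \code{cohort_incidence}.
#' @param path output file.
#' @export
write_cohort_incidence <- function(inc, path) {
  stopifnot(inherits(inc, "cohort_incidence"))
  utils::write.table(inc$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-year population hazard for one stratum
#'
#' Extracts the age 0--79 rate vector for a (cancer, sex) stratum and
#' converts rates per 100,000 to per-person-year probabilities.
#'
#' @param inc a \code{cohort_incidence}.
#' @param cancer,sex stratum selectors (sex may be omitted when unambiguous).
#' @return numeric vector of length 80.
#' @export
cohort_hazard <- function(inc, cancer, sex = NULL) {
  stopifnot(inherits(inc, "cohort_incidence"))
  s <- inc$table[inc$table$cancer == cancer, , drop = FALSE]
  if (!is.null(sex)) s <- s[s$sex == sex, , drop = FALSE]
  if (nrow(s) == 0L)
    stop(sprintf("cohort_hazard: no incidence for cancer '%s'%s", cancer,
                 if (is.null(sex)) "" else sprintf(" sex %s", sex)))
  if (length(unique(s$sex)) > 1L)
    stop(sprintf("cohort_hazard: cancer '%s' is ambiguous; give sex", cancer))
  s <- s[order(s$age), ]
  s$rate_per_100k / 1e5
}

#' Risk-profile distribution
#'
#' The joint population distribution at birth over risk profiles (major
#' genotype x polygene level x risk-factor bins), each with a probability
#' mass and a per-age relative-risk multiplier. This is the distribution
#' over which the baseline hazard is constrained.
#'
#' @param mass probability masses summing to 1 (zero masses allowed).
#' @param rr matrix (profiles x 80) of strictly positive RR multipliers.
#' @export
risk_profile_distribution <- function(mass, rr) {
  if (is.vector(rr)) rr <- matrix(rr, nrow = length(mass), ncol = 80)
  stopifnot(is.matrix(rr), nrow(rr) == length(mass), ncol(rr) == 80L)
  if (abs(sum(mass) - 1) > 1e-12)
    stop("risk_profile_distribution: masses must sum to 1 (within 1e-12)")
  if (any(mass < 0)) stop("risk_profile_distribution: negative mass")
  if (any(rr <= 0)) stop("risk_profile_distribution: RR must be positive")
  structure(list(mass = mass, rr = rr), class = "risk_profile_distribution")
}

#' Constrain the baseline hazard to population incidence
#'
#' Computes the baseline hazard \eqn{\lambda_0(t)} sequentially from age 0:
#' maintaining each profile's disease-free survival
#' \eqn{S_i(t) = \exp(-\sum_{u<t} \lambda_0(u) RR_i(u))}, the baseline at
#' age t is set to
#' \deqn{\lambda_0(t) = \lambda_{pop}(t) \frac{\sum_i m_i S_i(t)}{\sum_i m_i S_i(t) RR_i(t)}}
#' so that the population-averaged hazard among the disease-free equals the
#' population rate at every age.
#'
#' @param lambda_pop population hazard: numeric vector of length 80
#'   (per-person-year), or a \code{cohort_incidence} plus \code{cancer}/
#'   \code{sex}.
#' @param dist a \code{\link{risk_profile_distribution}}.
#' @param cancer,sex used when \code{lambda_pop} is a cohort table.
#' @return numeric vector of length 80 of class \code{baseline_hazard}.
#' @export
constrain_baseline <- function(lambda_pop, dist, cancer = NULL, sex = NULL) {
  if (inherits(lambda_pop, "cohort_incidence"))
    lambda_pop <- cohort_hazard(lambda_pop, cancer, sex)
  stopifnot(is.numeric(lambda_pop), length(lambda_pop) == 80L,
            inherits(dist, "risk_profile_distribution"))
  m <- dist$mass; rr <- dist$rr
  S <- rep(1, length(m))
  lam0 <- numeric(80)
  for (t in 1:80) {
    mS <- m * S
    den <- sum(mS * rr[, t])
    if (den <= 0)
      stop(sprintf("constrain_baseline: degenerate model at age %d (all mass exhausted)",
                   t - 1L))
    lam0[t] <- lambda_pop[t] * sum(mS) / den
    S <- S * exp(-lam0[t] * rr[, t])
  }
  structure(lam0, class = "baseline_hazard")
}

#' Population-averaged hazard implied by a baseline and profile distribution
#'
#' Verification helper: recomputes
#' \eqn{\sum_i m_i S_i(t) RR_i(t) \lambda_0(t) / \sum_i m_i S_i(t)}. After
#' \code{\link{constrain_baseline}} this equals the population hazard at
#' every age.
#'
#' @param baseline numeric length-80 baseline hazard.
#' @param dist a \code{\link{risk_profile_distribution}}.
#' @param t ages (0--79) at which to evaluate; default all.
#' @export
expected_population_hazard <- function(baseline, dist, t = 0:79) {
  stopifnot(all(t >= 0 & t <= 79),
            inherits(dist, "risk_profile_distribution"))
  m <- dist$mass; rr <- dist$rr
  S <- rep(1, length(m))
  out <- numeric(80)
  for (u in 1:80) {
    mS <- m * S
    out[u] <- sum(mS * rr[, u]) * baseline[u] / sum(mS)
    S <- S * exp(-baseline[u] * rr[, u])
  }
  out[t + 1L]
}
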