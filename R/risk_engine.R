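# Absolute risk prediction, risk categorisation and reclassification
# distributions.

#' Future absolute cancer risk for the target
#'
#' Posterior-weighted cumulative incidence from the target's current age to
#' a horizon: the genotype-state posterior is obtained by pedigree peeling
#' (conditioning on the full family history, tests, pathology, risk
#' factors and PRS), and each state contributes
#' \eqn{1 - \exp(-\sum_t \lambda_0(t) RR_{state}(t))}; the mixture updates
#' the disease-free state distribution age by age.
#'
#' @param ped a \code{\link{pedigree}}; the target must be unaffected for
#'   the predicted cancer.
#' @param model a \code{\link{risk_model}}.
#' @param cancer cancer to predict (default: the model's primary cancer).
#' @param horizon_age risk horizon (default 80).
#' @return object of class \code{risk_result}: data.frame \code{curve}
#'   (age, cumulative risk), \code{lifetime} (set when the curve spans
#'   20--80), \code{category}, and the target's carrier posteriors.
#' @export
future_risk <- function(ped, model, cancer = NULL, horizon_age = 80L) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "risk_model"))
  if (is.null(cancer)) cancer <- model$cancer
  ti <- ped_target(ped)
  row <- as.list(ped[ti, , drop = FALSE])
  sex_needed <- CANCER_SEX[[cancer]]
  if (sex_needed != "MF" && row$sex != sex_needed)
    stop(sprintf("future_risk: %s risk prediction requires a %s target",
                 cancer, sex_needed))
  dxcol <- individual_cancers(row$sex)
  dxcol <- dxcol[names(dxcol) == cancer]
  if (length(dxcol) && row[[dxcol]] > 0)
    stop(sprintf("target already affected with %s; secondary/contralateral risks are not modelled",
                 cancer))
  a <- min(floor(row$censor_age), 80L)
  if (horizon_age <= a) stop("future_risk: horizon_age must exceed current age")
  horizon_age <- min(horizon_age, 80L)

  key <- hazard_key(cancer, row$sex)
  lam0 <- model$baseline[[key]]
  if (is.null(lam0))
    stop(sprintf("no baseline hazard for cancer '%s'", cancer))
  post <- state_posterior(ped, model)
  srr <- model$state_rr[[cancer]]
  mult <- if (cancer == model$cancer) rf_multiplier(model, row) else 1

  ages <- a:(horizon_age - 1L)
  haz <- srr[, ages + 1L, drop = FALSE] *
    rep(lam0[ages + 1L], each = model$S) * mult
  cumhaz <- t(apply(haz, 1L, cumsum))
  curve_risk <- as.vector(post %*% (1 - exp(-cumhaz)))
  curve <- data.frame(age = c(a, ages + 1L), cum_risk = c(0, curve_risk))

  lifetime <- if (a <= 20L && horizon_age == 80L)
    curve$cum_risk[curve$age == 80L] else NA_real_
  category <- if (!is.na(lifetime) && !is.null(model$scheme) &&
                  cancer == model$cancer)
    categorize_risk(lifetime, model$scheme) else NA_character_
  structure(list(cancer = cancer, curve = curve, lifetime = lifetime,
                 category = category,
                 carrier_posterior = carrier_probabilities(ped, model)),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %s: risk to age %d = %.1f%%\n", x$cancer,
              max(x$curve$age), 100 * max(x$curve$cum_risk)))
  if (!is.na(x$lifetime))
    cat(sprintf("  lifetime (20-80): %.1f%%%s\n", 100 * x$lifetime,
                if (!is.na(x$category)) sprintf(" [%s]", x$category) else ""))
  invisible(x)
}

#' Lifetime (age 20--80) risk for an unaffected target
#'
#' \code{\link{future_risk}} specialised to the 20--80 window: the target
#' is treated as unaffected and censored at age 20.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @param cancer cancer to predict.
#' @return the lifetime risk (a fraction).
#' @export
lifetime_risk <- function(ped, model, cancer = NULL) {
  ti <- ped_target(ped)
  ped$censor_age[ti] <- 20
  ped <- pedigree(as.data.frame(ped))
  future_risk(ped, model, cancer, horizon_age = 80L)$lifetime
}

# reference pedigrees for reclassification distributions: a 1985-born
# female proband, optionally with a mother affected at 50
reference_pedigree <- function(model, gene = NULL, fh = c("unknown", "mother50"),
                               mother_censor_age = 55) {
  fh <- match.arg(fh)
  tcol <- paste0(model$gene_names, "_test")
  base <- data.frame(id = "proband", father = "0", mother = "0", sex = "F",
                     birth_year = 1985, censor_age = 20, target = 1L,
                     stringsAsFactors = FALSE)
  for (cl in tcol) base[[cl]] <- "0"
  if (!is.null(gene)) {
    if (!gene %in% model$gene_names)
      stop(sprintf("gene '%s' is not in the model", gene))
    base[[paste0(gene, "_test")]] <- "P"
  }
  if (fh == "unknown") return(pedigree(base))
  dxcol <- if (model$cancer == "bc") "bc_age" else "eoc_age"
  base[[dxcol]] <- 0
  mo <- data.frame(id = "mother", father = "0", mother = "0", sex = "F",
                   birth_year = 1955, censor_age = mother_censor_age,
                   target = 0L, stringsAsFactors = FALSE)
  fa <- data.frame(id = "father", father = "0", mother = "0", sex = "M",
                   birth_year = 1953, censor_age = 0, target = 0L,
                   stringsAsFactors = FALSE)
  for (cl in tcol) { mo[[cl]] <- "0"; fa[[cl]] <- "0" }
  mo[[dxcol]] <- 50
  fa[[dxcol]] <- 0
  base$father <- "father"; base$mother <- "mother"
  mo$father <- mo$mother <- fa$father <- fa$mother <- "0"
  pedigree(rbind(base[names(base)], mo[names(base)], fa[names(base)]))
}

#' Lifetime-risk distribution over unobserved risk predictors
#'
#' For a fixed carrier status and family history, enumerates the joint
#' population distribution of the selected predictors -- questionnaire risk
#' factors (\code{"qrf"}), mammographic density (\code{"md"}) and the PRS
#' (\code{"prs"}, integrated on a Gauss-Hermite grid) -- and computes the
#' lifetime risk at each combination via the full pedigree engine. The
#' result is the probability distribution of lifetime risk, with the
#' proportion falling in each risk category: the reclassification
#' distribution for that carrier group.
#'
#' @param model a \code{\link{risk_model}}.
#' @param gene carried gene (test-confirmed), or NULL for no genetic
#'   information.
#' @param fh \code{"unknown"} or \code{"mother50"} (mother affected with
#'   the model's primary cancer at age 50, censored at
#'   \code{mother_censor_age}).
#' @param factors subset of \code{c("qrf", "md", "prs", "height")}
#'   (height is enumerated over its discretisation bins).
#' @param prs_nodes Gauss-Hermite node count for the PRS integral
#'   (default 64).
#' @param mother_censor_age see \code{fh}.
#' @return object of class \code{risk_distribution}: data.frame
#'   \code{grid} (risk, mass), named \code{proportions} per category, and
#'   the mass-weighted \code{mean_risk}.
#' @export
risk_distribution <- function(model, gene = NULL,
                              fh = c("unknown", "mother50"),
                              factors = character(),
                              prs_nodes = 64L, mother_censor_age = 55) {
  fh <- match.arg(fh)
  stopifnot(all(factors %in% c("qrf", "md", "prs", "height")))
  for (f in setdiff(factors, "prs"))
    if (is.null(model$rfs[[f]]))
      stop(sprintf("risk_distribution: no population distribution for '%s' in the model",
                   f))
  ped <- reference_pedigree(model, gene, fh, mother_censor_age)
  ti <- ped_target(ped)

  levels <- list(none = data.frame(w = 1))
  grids <- list()
  if ("qrf" %in% factors)
    grids$qrf <- data.frame(qrf = seq_along(model$rfs$qrf$masses),
                            w_qrf = model$rfs$qrf$masses)
  if ("md" %in% factors)
    grids$md <- data.frame(md = seq_along(model$rfs$md$masses),
                           w_md = model$rfs$md$masses)
  if ("height" %in% factors) {
    hb <- model$rfs$height
    grids$height <- data.frame(height_bin = which(!hb$observed),
                               w_height = hb$mass[!hb$observed])
  }
  if ("prs" %in% factors) {
    gh <- pracma::gaussHermite(prs_nodes)
    grids$prs <- data.frame(prs_z = sqrt(2) * gh$x,
                            w_prs = gh$w / sqrt(pi))
  }
  combo <- Reduce(function(a, b) merge(a, b, by = NULL),
                  grids, accumulate = FALSE)
  if (is.null(combo)) combo <- data.frame(.dummy = 1)

  risks <- numeric(nrow(combo)); mass <- numeric(nrow(combo))
  for (i in seq_len(nrow(combo))) {
    p2 <- ped
    if (!is.null(combo$qrf)) p2$qrf[ti] <- combo$qrf[i]
    if (!is.null(combo$md)) p2$md[ti] <- combo$md[i]
    if (!is.null(combo$height_bin)) p2$height_bin[ti] <- combo$height_bin[i]
    if (!is.null(combo$prs_z)) p2$prs_z[ti] <- combo$prs_z[i]
    risks[i] <- lifetime_risk(p2, model)
    w <- 1
    for (wc in grep("^w_", names(combo), value = TRUE)) w <- w * combo[[wc]][i]
    mass[i] <- w
  }
  mass <- mass / sum(mass)
  o <- order(risks)
  grid <- data.frame(risk = risks[o], mass = mass[o])
  props <- if (!is.null(model$scheme)) {
    cats <- categorize_risk(grid$risk, model$scheme)
    vapply(model$scheme$labels, function(l) sum(grid$mass[cats == l]), 0)
  } else NULL
  structure(list(gene = if (is.null(gene)) "none" else gene, fh = fh,
                 factors = factors, grid = grid, proportions = props,
                 mean_risk = sum(grid$risk * grid$mass)),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("<risk_distribution> gene %s, FH %s, factors: %s\n", x$gene,
              x$fh, if (length(x$factors)) paste(x$factors, collapse = ",")
              else "none"))
  cat(sprintf("  mean lifetime risk %.1f%%; %d grid points\n",
              100 * x$mean_risk, nrow(x$grid)))
  if (!is.null(x$proportions))
    for (l in names(x$proportions))
      cat(sprintf("  %-16s %5.1f%%\n", l, 100 * x$proportions[[l]]))
  invisible(x)
}

#' Monte-Carlo sampler matching \code{\link{risk_distribution}}
#'
#' Draws predictor values from their population distributions (PRS from
#' N(0,1)), computes each sample's lifetime risk through the same engine,
#' and returns the sampled category proportions. Used as an independent
#' stochastic cross-check of the deterministic enumeration.
#'
#' @param model,gene,fh,factors,mother_censor_age as
#'   \code{\link{risk_distribution}}.
#' @param n number of samples.
#' @param seed RNG seed.
#' @export
sample_risk_distribution <- function(model, gene = NULL,
                                     fh = c("unknown", "mother50"),
                                     factors = character(), n = 400L,
                                     seed = 1L, mother_censor_age = 55) {
  fh <- match.arg(fh)
  set.seed(seed)
  ped <- reference_pedigree(model, gene, fh, mother_censor_age)
  ti <- ped_target(ped)
  risks <- numeric(n)
  for (i in seq_len(n)) {
    p2 <- ped
    if ("qrf" %in% factors)
      p2$qrf[ti] <- sample.int(length(model$rfs$qrf$masses), 1L,
                               prob = model$rfs$qrf$masses)
    if ("md" %in% factors)
      p2$md[ti] <- sample.int(length(model$rfs$md$masses), 1L,
                              prob = model$rfs$md$masses)
    if ("prs" %in% factors) p2$prs_z[ti] <- stats::rnorm(1L)
    risks[i] <- lifetime_risk(p2, model)
  }
  cats <- categorize_risk(risks, model$scheme)
  props <- vapply(model$scheme$labels, function(l) mean(cats == l), 0)
  list(risks = risks, proportions = props, n = n)
}
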