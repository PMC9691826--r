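# Observation likelihoods and exact pedigree likelihood by peeling
# (variable elimination over per-individual genotype states), with a
# brute-force enumeration cross-check.

#' Genetic-test likelihood
#'
#' Probability of a clinical test result given carrier status and the
#' screening sensitivity SS: a carrier tests positive with probability SS
#' and negative with 1 - SS; a non-carrier never tests positive
#' (specificity 1).
#'
#' @param result \code{"N"} (negative) or \code{"P"} (positive).
#' @param is_carrier logical: does the individual carry a PV in the tested
#'   gene?
#' @param sensitivity SS in (0, 1].
#' @export
test_likelihood <- function(result, is_carrier, sensitivity) {
  stopifnot(result %in% c("N", "P"), sensitivity > 0, sensitivity <= 1)
  if (is_carrier) {
    if (result == "P") sensitivity else 1 - sensitivity
  } else {
    if (result == "P") 0 else 1
  }
}

# which cancer phenotypes a pedigree row can express, with their dx columns
individual_cancers <- function(sex) {
  if (sex == "F")
    c(bc = "bc_age", eoc = "eoc_age", pancreas = "pancreas_age")
  else
    c(mbc = "bc_age", prostate = "prostate_age", pancreas = "pancreas_age")
}

# multiplier from the individual's observed risk factors (primary cancer)
rf_multiplier <- function(model, row) {
  mult <- 1
  hb <- model$rfs$height
  if (!is.null(hb) && !is.null(row$height) && !is.na(row$height)) {
    mult <- mult * rf_rr(attr(hb, "rf"), row$height) / attr(hb, "normaliser")
  } else if (!is.null(hb) && !is.null(row$height_bin) &&
             !is.na(row$height_bin) && row$height_bin > 0) {
    mult <- mult * hb$rr[row$height_bin]  # bin-averaged RR (enumeration)
  }
  for (nm in c("qrf", "md")) {
    rf <- model$rfs[[nm]]
    v <- row[[nm]]
    if (!is.null(rf) && !is.null(v) && !is.na(v) && v > 0) {
      if (v > length(rf$rr))
        stop(sprintf("individual %s: %s category %d out of range",
                     row$id, nm, v))
      mult <- mult * rf$rr[v]
    }
  }
  mult
}

pathology_code_to_category <- function(code) {
  # 0 none/ER unknown, 1 ER+, 2 ER-/TN unknown, 3 ER-/not TN, 4 TN
  PATHOLOGY_CATEGORIES[code + 1L]
}

# per-major-state pathology factor for a BC diagnosis at dx_age
pathology_state_factor <- function(model, code, dx_age) {
  if (code == 0L) return(rep(1, model$K + 1L))
  cat <- pathology_code_to_category(code)
  vapply(c("population", model$gene_names), function(g) {
    dist <- model$pathology[[g]]
    if (is.null(dist)) dist <- model$pathology$population
    pathology_category_prob(dist, cat, dx_age)
  }, 0)
}

#' Phenotype likelihood of one individual given a genotype state
#'
#' Product over the cancers modelled for the individual's sex of the
#' probability of the observed history under the state's hazard
#' \eqn{\lambda_0(t) RR_{state}(t)}: survival to the diagnosis or censoring
#' age, the hazard at the diagnosis age if affected, and the probability of
#' the observed tumour pathology category if recorded. Genetic tests and a
#' measured PRS are handled separately (see
#' \code{\link{observation_likelihoods}}).
#'
#' @param row a single-row piece of a \code{\link{pedigree}} (list-like).
#' @param gene carried gene name, or \code{"none"}.
#' @param level polygene level index (1-based).
#' @param model a \code{\link{risk_model}}.
#' @export
phenotype_likelihood <- function(row, gene, level, model) {
  g <- if (identical(gene, "none")) 0L else match(gene, model$gene_names)
  if (is.na(g)) stop(sprintf("unknown gene '%s'", gene))
  s <- g * model$pg$n_levels + level
  unname(obs_likelihood_row(model, row, phenotype_only = TRUE)[s])
}

# S-vector of observation likelihood for one pedigree row
obs_likelihood_row <- function(model, row, phenotype_only = FALSE) {
  S <- model$S
  L <- rep(1, S)
  a <- min(floor(row$censor_age), 80)
  for (cn in names(individual_cancers(row$sex))) {
    dxcol <- individual_cancers(row$sex)[[cn]]
    dx <- floor(row[[dxcol]])
    key <- hazard_key(cn, row$sex)
    lam0 <- model$baseline[[key]]
    if (is.null(lam0)) {
      if (dx > 0)
        stop(sprintf("no baseline hazard for observed cancer '%s' (individual %s)",
                     cn, row$id))
      next  # unobserved cancer without incidence: uninformative
    }
    srr <- model$state_rr[[cn]]
    mult <- if (cn == model$cancer) rf_multiplier(model, row) else 1
    t_end <- if (dx > 0) min(dx, 80L) else a
    if (t_end > 0) {
      H <- as.vector(srr[, seq_len(t_end), drop = FALSE] %*%
                       lam0[seq_len(t_end)]) * mult
      L <- L * exp(-H)
    }
    if (dx > 0) {
      ti <- min(dx, 79L) + 1L
      L <- L * lam0[ti] * srr[, ti] * mult
      if (cn == "bc" && row$pathology > 0L) {
        pf <- pathology_state_factor(model, row$pathology, dx)
        L <- L * pf[model$state_gene + 1L]
      }
    }
  }
  if (phenotype_only) return(L)
  # genetic tests
  tests <- ped_gene_tests(row)
  for (g in names(tests)) {
    res <- as.character(row[[tests[[g]]]])
    if (is.na(res) || res == "0") next
    gi <- match(g, model$gene_names)
    if (is.na(gi)) next  # test for a gene outside this model: uninformative
    carrier <- model$state_gene == gi
    fac <- ifelse(carrier,
                  test_likelihood(res, TRUE, model$sens[[g]]),
                  test_likelihood(res, FALSE, model$sens[[g]]))
    L <- L * fac
  }
  if (!is.null(row$prs_z) && !is.na(row$prs_z))
    L <- L * prs_obs_likelihood(model$pg, row$prs_z)[model$state_level]
  unname(L)
}

#' Observation likelihood matrix for a pedigree
#'
#' One row per individual, one column per genotype state (collapsed major
#' genotype x polygene level), combining phenotypes, tumour pathology,
#' genetic tests and measured PRS.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @export
observation_likelihoods <- function(ped, model) {
  out <- matrix(NA_real_, nrow(ped), model$S,
                dimnames = list(ped$id, NULL))
  for (i in seq_len(nrow(ped)))
    out[i, ] <- obs_likelihood_row(model, as.list(ped[i, , drop = FALSE]))
  out
}

# ---- variable elimination over individuals -------------------------------

joint_transmission <- function(model) {
  if (!is.null(.famrisk_env$joint_key) &&
      identical(.famrisk_env$joint_key, list(model$gene_names,
                                             model$pg$n_levels,
                                             model$prior_major))) {
    return(.famrisk_env$joint_T)
  }
  gidx <- model$state_gene + 1L
  lidx <- model$state_level
  TA <- model$major_kernel[gidx, gidx, gidx]
  TB <- model$pg_kernel[lidx, lidx, lidx]
  Tj <- TA * TB
  .famrisk_env$joint_key <- list(model$gene_names, model$pg$n_levels,
                                 model$prior_major)
  .famrisk_env$joint_T <- Tj
  Tj
}

founder_prior_states <- function(model) {
  model$prior_major[model$state_gene + 1L] * model$pg$masses[model$state_level]
}

build_factors <- function(ped, model, obs = NULL) {
  if (is.null(obs)) obs <- observation_likelihoods(ped, model)
  S <- model$S
  Tj <- NULL
  factors <- list()
  prior <- founder_prior_states(model)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (ped$father[i] == "0") {
      factors[[length(factors) + 1L]] <-
        list(vars = id, tab = prior * obs[i, ])
    } else {
      if (is.null(Tj)) Tj <- joint_transmission(model)
      if (as.double(S)^3 > model$state_cap)
        stop("genotype state space too large for peeling; reduce the number of polygene levels or genes")
      factors[[length(factors) + 1L]] <-
        list(vars = c(id, ped$father[i], ped$mother[i]),
             tab = Tj * obs[i, ])   # obs recycles down the child dimension
    }
  }
  factors
}

expand_to <- function(f, vars_u, S) {
  extra <- setdiff(vars_u, f$vars)
  tab <- f$tab
  nf <- length(f$vars)
  if (length(extra)) {
    tab <- array(rep(as.vector(tab), S^length(extra)),
                 dim = c(rep(S, nf), rep(S, length(extra))))
  } else if (nf > 1L) {
    dim(tab) <- rep(S, nf)
  }
  cur <- c(f$vars, extra)
  if (length(vars_u) > 1L) tab <- aperm(tab, match(vars_u, cur))
  tab
}

eliminate_var <- function(factors, var, S, cap) {
  touch <- vapply(factors, function(f) var %in% f$vars, TRUE)
  fs <- factors[touch]
  vars_u <- unique(unlist(lapply(fs, `[[`, "vars")))
  if (S^length(vars_u) > cap)
    stop("genotype state space too large for peeling; reduce the number of polygene levels or genes")
  tab <- expand_to(fs[[1L]], vars_u, S)
  for (f in fs[-1L]) tab <- tab * expand_to(f, vars_u, S)
  i <- match(var, vars_u)
  perm <- c(i, setdiff(seq_along(vars_u), i))
  if (length(vars_u) > 1L) {
    tab <- aperm(tab, perm)
    dim(tab) <- c(S, length(tab) / S)
    res <- colSums(tab)
    rem <- vars_u[-i]
    if (length(rem) > 1L) dim(res) <- rep(S, length(rem))
  } else {
    res <- sum(tab)
    rem <- character(0)
  }
  c(factors[!touch], list(list(vars = rem, tab = res)))
}

ve_run <- function(factors, keep, S, cap) {
  all_vars <- unique(unlist(lapply(factors, `[[`, "vars")))
  elim <- setdiff(all_vars, keep)
  while (length(elim)) {
    # greedy: eliminate the variable with the smallest combined scope
    width <- vapply(elim, function(v) {
      vs <- unique(unlist(lapply(factors,
                                 function(f) if (v %in% f$vars) f$vars)))
      length(vs)
    }, 0L)
    v <- elim[which.min(width)]
    factors <- eliminate_var(factors, v, S, cap)
    elim <- setdiff(elim, v)
  }
  # combine what remains
  scal <- vapply(factors, function(f) length(f$vars) == 0L, TRUE)
  const <- prod(vapply(factors[scal], function(f) as.numeric(f$tab), 0),
                1)
  rest <- factors[!scal]
  if (length(rest) == 0L) return(const)
  vars_u <- unique(unlist(lapply(rest, `[[`, "vars")))
  tab <- expand_to(rest[[1L]], vars_u, S)
  for (f in rest[-1L]) tab <- tab * expand_to(f, vars_u, S)
  tab * const
}

#' Pedigree likelihood by peeling
#'
#' Exact sum over all joint genotype-state assignments of founder priors,
#' Mendelian/polygenic transmission probabilities and observation
#' likelihoods, computed by variable elimination over the pedigree graph.
#' Equals \code{\link{enumerate_pedigree_likelihood}} on any pedigree small
#' enough to enumerate.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @return the total likelihood (a scalar).
#' @export
peel_likelihood <- function(ped, model) {
  stopifnot(inherits(ped, "pedigree"), inherits(model, "risk_model"))
  as.numeric(ve_run(build_factors(ped, model), character(0), model$S,
                    model$state_cap))
}

#' Pedigree likelihood by exhaustive enumeration
#'
#' Brute-force oracle: sums founder priors x transmission x observation
#' over every joint assignment of genotype states to individuals. Only
#' feasible for small pedigrees; used to validate the peeling algorithm.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @param max_states refuse above this many joint assignments.
#' @export
enumerate_pedigree_likelihood <- function(ped, model, max_states = 2e7) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped); S <- model$S
  if (as.double(S)^n > max_states)
    stop("enumeration infeasible: too many joint states")
  obs <- observation_likelihoods(ped, model)
  prior <- founder_prior_states(model)
  Tj <- joint_transmission(model)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n),
                                KEEP.OUT.ATTRS = FALSE))
  p <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    si <- grid[, i]
    p <- p * obs[i, si]
    if (ped$father[i] == "0") {
      p <- p * prior[si]
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      p <- p * Tj[cbind(si, grid[, fi], grid[, mi])]
    }
  }
  sum(p)
}

#' Posterior genotype-state distribution of one individual
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @param id individual (default: the target).
#' @return numeric length-S vector summing to 1.
#' @export
state_posterior <- function(ped, model, id = NULL) {
  if (is.null(id)) id <- ped$id[ped_target(ped)]
  stopifnot(id %in% ped$id)
  tab <- ve_run(build_factors(ped, model), id, model$S, model$state_cap)
  tot <- sum(tab)
  if (tot <= 0)
    stop("zero pedigree likelihood: the observations are mutually inconsistent under the model")
  as.numeric(tab) / tot
}

#' Pathogenic-variant carrier probabilities for the target
#'
#' Posterior probability that the target carries a PV in each modelled
#' gene, given the full pedigree: phenotypes, ages, genetic tests, tumour
#' pathology and PRS. The probabilities over the collapsed genotype states
#' (non-carrier plus one per gene) sum to 1.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param model a \code{\link{risk_model}}.
#' @param id individual (default: the target).
#' @return named numeric vector: \code{noncarrier}, then one entry per gene.
#' @export
carrier_probabilities <- function(ped, model, id = NULL) {
  post <- state_posterior(ped, model, id)
  agg <- vapply(0:model$K, function(g)
    sum(post[model$state_gene == g]), 0)
  stats::setNames(agg, c("noncarrier", model$gene_names))
}
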