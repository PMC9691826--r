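# Discretised polygenic component: binomial level grid, hypergeometric
# parent-offspring transmission, variance adjustment for newly added major
# genes, and conditioning on a measured polygenic risk score.

#' Discretise the polygenic component
#'
#' The latent standard-normal polygenotype is approximated by the
#' standardised sum of \code{n_levels - 1} equifrequent biallelic doses:
#' masses follow Binomial(n_levels - 1, 1/2) and the level values are the
#' symmetric grid standardised to mean 0, variance 1 (both exact).
#'
#' @param n_levels odd integer >= 3.
#' @return list with \code{values} and \code{masses}.
#' @export
discretise_polygene <- function(n_levels) {
  if (length(n_levels) != 1L || n_levels < 3L || n_levels %% 2L == 0L)
    stop("discretise_polygene: n_levels must be an odd integer >= 3")
  k <- 0:(n_levels - 1L)
  list(values = (k - (n_levels - 1L) / 2) / sqrt((n_levels - 1L) / 4),
       masses = stats::dbinom(k, n_levels - 1L, 0.5))
}

#' Polygene model
#'
#' The polygenic log-relative-hazard at age t is sigma_P(t) times the
#' standardised discrete level; sigma_P(t) is the age-specific SD of the
#' polygenic component and alpha2 the fraction of its variance explained by
#' the measured PRS (0.20 for the breast-cancer PRS, 0.05 for the
#' tubo-ovarian PRS).
#'
#' @param sd sigma_P(t): positive scalar or length-80 vector.
#' @param n_levels odd number of discretisation levels (default 7).
#' @param alpha2 fraction of polygenic variance explained by the PRS.
#' @export
polygene_model <- function(sd = 1, n_levels = 7L, alpha2 = 0) {
  if (any(sd <= 0)) stop("polygene_model: sd must be positive")
  if (alpha2 < 0 || alpha2 > 1) stop("polygene_model: alpha2 must lie in [0,1]")
  sd <- rep_len(sd, 80L)
  d <- discretise_polygene(n_levels)
  structure(list(sd = sd, n_levels = as.integer(n_levels), alpha2 = alpha2,
                 values = d$values, masses = d$masses),
            class = "polygene_model")
}

#' Per-age polygenic relative risks
#'
#' RR of level k at age t is exp(sigma_P(t) * v_k) divided by the
#' population mean over the discrete distribution, so the population-mean
#' polygenic RR is exactly 1 at every age.
#'
#' @param pg a \code{\link{polygene_model}}.
#' @return matrix (n_levels x 80).
#' @export
polygene_rr_matrix <- function(pg) {
  stopifnot(inherits(pg, "polygene_model"))
  raw <- exp(outer(pg$values, pg$sd))
  sweep(raw, 2, colSums(raw * pg$masses), "/")
}

#' Parent-offspring transmission of the discrete polygene
#'
#' Hypergeometric polygenic transmission: each parent passes half of their
#' \code{n_levels - 1} dose slots, drawn without replacement, and the child
#' level is the sum of the two transmitted halves. The child's expectation
#' is the midparent mean and the binomial founder distribution is
#' stationary across generations.
#'
#' @param n_levels odd integer >= 3.
#' @return array (child, father, mother) of transmission probabilities.
#' @export
polygene_transmission <- function(n_levels) {
  if (n_levels < 3L || n_levels %% 2L == 0L)
    stop("polygene_transmission: n_levels must be an odd integer >= 3")
  L <- as.integer(n_levels)
  doses <- L - 1L            # total dose slots per parent
  half <- doses %/% 2L       # slots transmitted
  gam <- matrix(0, L, half + 1L)  # gam[f+1, x+1] = P(transmit x | parent f)
  for (f in 0:doses)
    gam[f + 1L, ] <- stats::dhyper(0:half, f, doses - f, half)
  K <- array(0, dim = c(L, L, L))
  for (f in 0:doses) for (m in 0:doses) {
    child <- outer(gam[f + 1L, ], gam[m + 1L, ])  # x_f by x_m
    for (x in 0:half) for (yx in 0:half) {
      cval <- x + yx
      K[cval + 1L, f + 1L, m + 1L] <- K[cval + 1L, f + 1L, m + 1L] +
        child[x + 1L, yx + 1L]
    }
  }
  K
}

#' Variance contribution of a major gene to the polygenic component
#'
#' The per-age variance of a gene's log-RR contribution is
#' \eqn{v_g(t) = p(1-p)\,\ln^2 RR_g(t)} with p the gene's carrier
#' probability; the summary \code{v_bar} averages over ages weighted by the
#' supplied incidence weights.
#'
#' @param gene a \code{\link{gene_params}}.
#' @param cancer cancer type whose RRs are used.
#' @param weights length-80 non-negative weights summing to 1 (typically
#'   normalised age-specific incidence).
#' @return list with \code{gene}, \code{v_by_age} (length 80), \code{v_bar}.
#' @export
gene_log_rr_variance <- function(gene, cancer, weights) {
  stopifnot(inherits(gene, "gene_params"), length(weights) == 80L,
            all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("gene_log_rr_variance: weights must sum to 1")
  p <- carrier_prob(gene)
  v <- p * (1 - p) * log(rr_vector(gene, cancer))^2
  list(gene = gene$name, v_by_age = v, v_bar = sum(weights * v))
}

#' Incidence weights for variance averaging
#'
#' Normalises a stratum's age-specific incidence into weights for
#' \code{\link{gene_log_rr_variance}}.
#'
#' @param inc a \code{cohort_incidence} (or length-80 hazard vector).
#' @param cancer,sex stratum selectors.
#' @export
incidence_weights <- function(inc, cancer = NULL, sex = NULL) {
  lam <- if (inherits(inc, "cohort_incidence"))
    cohort_hazard(inc, cancer, sex) else inc
  stopifnot(length(lam) == 80L, all(lam >= 0), sum(lam) > 0)
  lam / sum(lam)
}

#' Adjust the polygenic SD for newly added major genes
#'
#' When genes previously absorbed by the polygenic component become
#' explicit major genes, their variance is removed so that the total
#' variance of the new polygenic component plus the new genes equals the
#' old polygenic variance:
#' \eqn{\sigma_{new}(t) = \sqrt{\sigma_{old}^2(t) - \sum_g v_g(t)}}.
#'
#' @param sd_old previous sigma_P(t): scalar or length-80 vector.
#' @param contributions list of \code{\link{gene_log_rr_variance}} results
#'   (possibly empty).
#' @return length-80 vector of adjusted SDs.
#' @export
adjust_polygenic_sd <- function(sd_old, contributions = list()) {
  sd_old <- rep_len(sd_old, 80L)
  if (any(sd_old <= 0)) stop("adjust_polygenic_sd: sd_old must be positive")
  vtot <- rep(0, 80L)
  for (ct in contributions) vtot <- vtot + ct$v_by_age
  if (any(vtot >= sd_old^2))
    stop(sprintf("adjust_polygenic_sd: variance deficit at age %d (gene variance %.3g >= polygenic variance %.3g)",
                 which(vtot >= sd_old^2)[1L] - 1L,
                 max(vtot), min(sd_old^2)))
  sqrt(sd_old^2 - vtot)
}

#' Condition the polygene on a measured PRS
#'
#' With the PRS explaining a fraction alpha2 of the polygenic variance, the
#' residual polygenotype given PRS z-score z has mean
#' \eqn{\alpha z \sigma_P(t)} and SD \eqn{\sqrt{1-\alpha^2}\,\sigma_P(t)}
#' (\eqn{\alpha = \sqrt{\alpha^2}}), realised as a shift/scale of the
#' discretised level values on the log-RR scale; the masses are unchanged.
#' Relative risks derived from the conditioned distribution keep the
#' unconditioned population normaliser, so the population-mean RR over the
#' unconditioned distribution remains 1.
#'
#' @param pg a \code{\link{polygene_model}}.
#' @param z measured PRS z-score (finite).
#' @param age age at which sigma_P is taken (default 0; with a constant
#'   sigma_P the age is immaterial).
#' @return list with \code{values} (log-RR scale), \code{masses},
#'   \code{mean}, \code{sd}.
#' @export
condition_on_prs <- function(pg, z, age = 0) {
  stopifnot(inherits(pg, "polygene_model"), is.finite(z),
            age >= 0, age <= 79)
  a <- sqrt(pg$alpha2)
  s <- pg$sd[age + 1L]
  vals <- s * (a * z + sqrt(1 - pg$alpha2) * pg$values)
  list(values = vals, masses = pg$masses,
       mean = a * z * s, sd = sqrt(1 - pg$alpha2) * s)
}

# PRS observation likelihood on the polygene level: z | v ~ N(alpha v, 1-alpha^2)
# on the standardised scale. Equivalent, in the continuous limit, to the
# shift/scale conditioning above; used when peeling pedigrees.
prs_obs_likelihood <- function(pg, z) {
  a <- sqrt(pg$alpha2)
  if (pg$alpha2 >= 1)
    return(as.numeric(abs(z - pg$values) < 1e-9))
  stats::dnorm(z, mean = a * pg$values, sd = sqrt(1 - pg$alpha2))
}
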