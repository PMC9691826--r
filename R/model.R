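# Assembled risk model: collapsed major-genotype space, polygene, risk
# factors, and baseline hazards constrained to cohort incidence.

hazard_key <- function(cancer, sex) {
  if (cancer == "pancreas") paste0("pancreas_", sex) else cancer
}

#' Major-genotype transmission kernel
#'
#' Transmission probabilities over the collapsed major-genotype space
#' {non-carrier, carrier-of-gene-1, ..., carrier-of-gene-K}. Each carrier
#' state is expanded internally into heterozygote/homozygote allele counts
#' under Hardy-Weinberg (so a carrier parent transmits their gene's PV
#' allele with probability q/(q(2-q)) = 1/(2-q)), the child's transmitted
#' allele set is formed Mendelianly, and multi-gene children are
#' re-collapsed to their highest-dominance gene.
#'
#' @param genes list of \code{\link{gene_params}} in dominance order.
#' @return array (child, father, mother) of size (K+1)^3.
#' @export
major_transmission_kernel <- function(genes) {
  K <- length(genes)
  q <- vapply(genes, function(g) g$allele_freq, 0)
  tau <- c(0, 1 / (2 - q))       # P(parent in state g transmits g's allele)
  Kn <- K + 1L
  A <- array(0, dim = c(Kn, Kn, Kn))
  for (f in 0:K) for (m in 0:K) {
    pf <- tau[f + 1L]; pm <- tau[m + 1L]
    # father transmits gene f (or nothing), mother gene m (or nothing)
    add <- function(child, p) A[child + 1L, f + 1L, m + 1L] <<-
      A[child + 1L, f + 1L, m + 1L] + p
    add(0L, (1 - pf) * (1 - pm))
    if (f > 0) add(f, pf * (1 - pm))
    if (m > 0) add(m, (1 - pf) * pm)
    if (f > 0 && m > 0) add(min(f, m), pf * pm)  # dominance collapse
  }
  A
}

# founder prior over collapsed states: carrier-of-g means g is the carried
# gene of highest dominance; independent HWE carriage across genes
major_founder_prior <- function(genes) {
  cp <- vapply(genes, carrier_prob, 0)
  K <- length(genes)
  pr <- numeric(K + 1L)
  pr[1L] <- prod(1 - cp)
  for (g in seq_len(K))
    pr[g + 1L] <- cp[g] * prod(1 - cp[seq_len(g - 1L)])
  pr / sum(pr)
}

#' Build a risk model
#'
#' Combines the gene registry, polygene, risk factors and cohort incidence
#' into a ready-to-use model for one primary cancer: genotype state space
#' (collapsed major genotype x polygene level), transmission kernels,
#' per-cancer relative-risk matrices, and baseline hazards constrained so
#' the population-averaged incidence reproduces the cohort rates. The
#' primary cancer's baseline is constrained over the full joint profile
#' distribution (major genotype x polygene x all risk-factor bins);
#' associated cancers (male breast, prostate, pancreatic, and the other
#' model's primary) are constrained over the major genotypes only and enter
#' relatives' likelihoods with their published RRs.
#'
#' @param config a \code{\link{load_model_config}} result.
#' @param incidence a \code{cohort_incidence} covering the strata to model.
#' @param cancer primary cancer: \code{"bc"} or \code{"eoc"}.
#' @param genes optional subset of gene names (default: the model's full
#'   gene set from the config).
#' @param n_polygene_levels override the config's polygene level count.
#' @param use_risk_factors include the configured risk factors in the
#'   primary profile distribution (default TRUE).
#' @param state_cap cap on elements of any single peeling factor.
#' @return object of class \code{risk_model}.
#' @export
risk_model <- function(config, incidence, cancer = c("bc", "eoc"),
                       genes = NULL, n_polygene_levels = NULL,
                       use_risk_factors = TRUE, state_cap = 2e7) {
  cancer <- match.arg(cancer)
  stopifnot(inherits(config, "model_config"),
            inherits(incidence, "cohort_incidence"))
  gl <- config$genes[[cancer]]
  if (is.null(gl)) stop(sprintf("config has no gene set for model '%s'", cancer))
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(gl))
    if (length(missing))
      stop(sprintf("genes not in the %s model: %s", cancer,
                   paste(missing, collapse = ", ")))
    gl <- gl[names(gl) %in% genes]
  }
  K <- length(gl)
  gene_names <- names(gl)

  L <- if (is.null(n_polygene_levels)) config$polygene$n_levels
       else n_polygene_levels
  alpha2 <- config$polygene$alpha2[[cancer]]
  if (is.null(alpha2)) alpha2 <- 0
  pg <- polygene_model(sd = config$polygene$sd, n_levels = L,
                       alpha2 = alpha2)
  pg_rr <- polygene_rr_matrix(pg)

  S <- (K + 1L) * L
  state_gene <- rep(0:K, each = L)       # 0 = non-carrier
  state_level <- rep(seq_len(L), times = K + 1L)

  rr_major <- list()
  for (cn in CANCER_TYPES) {
    mat <- matrix(1, nrow = K + 1L, ncol = 80L)
    for (g in seq_len(K)) mat[g + 1L, ] <- rr_vector(gl[[g]], cn)
    rr_major[[cn]] <- mat
  }

  # per-state RR matrices: polygene multiplies the primary cancer only
  state_rr <- list()
  for (cn in CANCER_TYPES) {
    m <- rr_major[[cn]][state_gene + 1L, , drop = FALSE]
    if (cn == cancer) m <- m * pg_rr[state_level, , drop = FALSE]
    state_rr[[cn]] <- m
  }

  prior_major <- major_founder_prior(gl)

  rfs <- list()
  if (use_risk_factors) {
    for (nm in names(config$risk_factors)) {
      rf <- config$risk_factors[[nm]]
      if (inherits(rf, "continuous_rf")) {
        rfs[[nm]] <- discretise_rf(rf)
      } else {
        rr_norm <- rf$rr / sum(rf$masses * rf$rr)
        rfs[[nm]] <- list(type = "categorical", name = nm,
                          masses = rf$masses, rr = rr_norm)
      }
    }
  }

  # joint profile distribution for the primary cancer's constraining
  comp_mass <- list(major = prior_major, polygene = pg$masses)
  comp_rr <- list(major = rr_major[[cancer]],
                  polygene = pg_rr)
  for (nm in names(rfs)) {
    rf <- rfs[[nm]]
    if (inherits(rf, "rf_bin_set")) {
      comp_mass[[nm]] <- rf$mass
      comp_rr[[nm]] <- matrix(rf$rr, nrow = nrow(rf), ncol = 80L)
    } else {
      comp_mass[[nm]] <- rf$masses
      comp_rr[[nm]] <- matrix(rf$rr, nrow = length(rf$rr), ncol = 80L)
    }
  }
  idx <- expand.grid(lapply(comp_mass, seq_along), KEEP.OUT.ATTRS = FALSE)
  pmass <- Reduce(`*`, lapply(names(comp_mass),
                              function(nm) comp_mass[[nm]][idx[[nm]]]))
  prr <- Reduce(`*`, lapply(names(comp_rr),
                            function(nm) comp_rr[[nm]][idx[[nm]], ,
                                                       drop = FALSE]))
  profile_dist <- risk_profile_distribution(pmass, prr)

  # baseline hazards per available incidence stratum
  strata <- unique(incidence$table[, c("sex", "cancer")])
  baseline <- list(); lambda_pop <- list()
  for (i in seq_len(nrow(strata))) {
    cn <- strata$cancer[i]; sx <- strata$sex[i]
    if (!cn %in% CANCER_TYPES) next
    key <- hazard_key(cn, sx)
    lam <- cohort_hazard(incidence, cn, sx)
    dist <- if (cn == cancer) profile_dist
            else risk_profile_distribution(prior_major, rr_major[[cn]])
    lambda_pop[[key]] <- lam
    baseline[[key]] <- constrain_baseline(lam, dist)
  }
  if (is.null(baseline[[cancer]]))
    stop(sprintf("incidence table lacks the primary cancer stratum '%s'",
                 cancer))

  structure(list(
    cancer = cancer, genes = gl, gene_names = gene_names, K = K,
    prior_major = prior_major,
    major_kernel = major_transmission_kernel(gl),
    pg = pg, pg_rr = pg_rr, pg_kernel = polygene_transmission(L),
    S = S, state_gene = state_gene, state_level = state_level,
    rr_major = rr_major, state_rr = state_rr,
    lambda_pop = lambda_pop, baseline = baseline,
    profile_dist = profile_dist,
    sens = vapply(gl, function(g) g$sensitivity, 0),
    pathology = config$pathology,
    rfs = rfs,
    scheme = config$categories[[cancer]],
    state_cap = state_cap), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> primary cancer: %s\n", x$cancer))
  cat(sprintf("  genes (dominance order): %s\n",
              paste(x$gene_names, collapse = " > ")))
  cat(sprintf("  polygene: %d levels, alpha2 = %g\n", x$pg$n_levels,
              x$pg$alpha2))
  cat(sprintf("  genotype states: %d; incidence strata: %s\n", x$S,
              paste(names(x$baseline), collapse = ", ")))
  if (length(x$rfs))
    cat(sprintf("  risk factors: %s\n", paste(names(x$rfs), collapse = ", ")))
  invisible(x)
}

.famrisk_env <- new.env(parent = emptyenv())

#' Default model on shipped parameters and synthetic incidence
#'
#' Builds (and caches) a \code{\link{risk_model}} from the shipped
#' configuration -- published gene table, synthetic pathology, polygene and
#' risk-factor fixtures -- and the shipped synthetic 1985-cohort incidence.
#' Suitable for tests and demonstration, not for clinical use.
#'
#' @param cancer \code{"bc"} or \code{"eoc"}.
#' @param ... passed to \code{\link{risk_model}}.
#' @export
default_model <- function(cancer = c("bc", "eoc"), ...) {
  cancer <- match.arg(cancer)
  extra <- list(...)
  key <- paste0("default_", cancer)
  if (length(extra) == 0L && !is.null(.famrisk_env[[key]]))
    return(.famrisk_env[[key]])
  config <- load_model_config()
  inc <- read_cohort_incidence(system.file("extdata",
                                           "synthetic_incidence_1985.tsv",
                                           package = "famrisk",
                                           mustWork = TRUE))
  m <- risk_model(config, inc, cancer = cancer, ...)
  if (length(extra) == 0L) .famrisk_env[[key]] <- m
  m
}
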