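# Gene-level model parameters: allele frequencies, screening sensitivities,
# age-piecewise relative risks, tumour pathology distributions and risk
# category schemes.

#' Cancer types modelled
#'
#' Codes for the cancer phenotypes entering the likelihood: female breast
#' cancer (\code{"bc"}), epithelial tubo-ovarian cancer (\code{"eoc"}), male
#' breast cancer (\code{"mbc"}), prostate and pancreatic cancer.
#' @export
CANCER_TYPES <- c("bc", "eoc", "mbc", "prostate", "pancreas")

# sex to which each cancer phenotype can apply
CANCER_SEX <- c(bc = "F", eoc = "F", mbc = "M", prostate = "M", pancreas = "MF")

#' Five-level tumour pathology observation scheme
#'
#' Breast tumours are classified by oestrogen-receptor (ER) and
#' triple-negative (TN) status into: ER unknown, ER-positive,
#' ER-negative/TN-unknown, ER-negative/not-TN and TN.
#' @export
PATHOLOGY_CATEGORIES <- c("ER:unknown", "ER+", "ER-/TN:unknown",
                          "ER-/not-TN", "TN")

MODEL_AGES <- 0:79

#' Age-piecewise relative risk function
#'
#' Relative risks of the major genes are piecewise functions of age over
#' 0--79, each segment either a constant or log-linear, exp(u + v * age).
#' Ages not covered by any segment default to RR = 1.
#'
#' @param segments data.frame with columns \code{age_lo}, \code{age_hi}
#'   (inclusive integer bounds), \code{form} (\code{"constant"} or
#'   \code{"loglinear"}), \code{c} (the constant), \code{u}, \code{v}
#'   (log-linear coefficients).
#' @return An object of class \code{age_piecewise_rr}.
#' @export
age_piecewise_rr <- function(segments) {
  if (nrow(segments) == 0L) {
    segments <- data.frame(age_lo = 0L, age_hi = 79L, form = "constant",
                           c = 1, u = NA_real_, v = NA_real_)
  }
  segments <- segments[order(segments$age_lo), , drop = FALSE]
  stopifnot(all(segments$form %in% c("constant", "loglinear")),
            all(segments$age_lo <= segments$age_hi),
            all(segments$age_lo >= 0), all(segments$age_hi <= 79))
  # no overlaps
  if (nrow(segments) > 1L &&
      any(segments$age_lo[-1L] <= segments$age_hi[-nrow(segments)]))
    stop("age_piecewise_rr: overlapping age segments")
  # fill gaps with RR = 1
  covered <- rep(FALSE, 80L)
  for (i in seq_len(nrow(segments)))
    covered[(segments$age_lo[i]:segments$age_hi[i]) + 1L] <- TRUE
  rr <- rep(1, 80L)
  for (i in seq_len(nrow(segments))) {
    ages <- segments$age_lo[i]:segments$age_hi[i]
    rr[ages + 1L] <- if (segments$form[i] == "constant") segments$c[i]
                     else exp(segments$u[i] + segments$v[i] * ages)
  }
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("age_piecewise_rr: RR must be finite and strictly positive at all ages")
  structure(list(segments = segments, rr = rr), class = "age_piecewise_rr")
}

#' Major-gene parameters
#'
#' A single susceptibility gene: general-population pathogenic-variant (PV)
#' allele frequency, clinical screening-test sensitivity, dominance rank and
#' age-piecewise relative risks per cancer type. Cancers absent from
#' \code{rr} are treated as RR = 1 at all ages.
#'
#' @param name gene symbol.
#' @param allele_freq PV allele frequency, in (0, 0.01).
#' @param sensitivity probability a clinical test detects a PV in a true
#'   carrier, in (0, 1].
#' @param dominance_rank integer rank; 1 is most dominant. Multi-gene
#'   carriers are collapsed to their highest-ranked gene.
#' @param rr named list of \code{\link{age_piecewise_rr}} objects, names in
#'   \code{\link{CANCER_TYPES}}.
#' @return An object of class \code{gene_params}.
#' @export
gene_params <- function(name, allele_freq, sensitivity, dominance_rank = 1L,
                        rr = list()) {
  if (!is.numeric(allele_freq) || allele_freq <= 0 || allele_freq >= 0.01)
    stop(sprintf("gene %s: allele_freq must lie in (0, 0.01), got %g",
                 name, allele_freq))
  if (!is.numeric(sensitivity) || sensitivity <= 0 || sensitivity > 1)
    stop(sprintf("gene %s: sensitivity must lie in (0, 1], got %g",
                 name, sensitivity))
  if (length(rr) && (!all(names(rr) %in% CANCER_TYPES) ||
                     !all(vapply(rr, inherits, TRUE, "age_piecewise_rr"))))
    stop(sprintf("gene %s: rr must be a named list of age_piecewise_rr over %s",
                 name, paste(CANCER_TYPES, collapse = ", ")))
  structure(list(name = name, allele_freq = allele_freq,
                 sensitivity = sensitivity,
                 dominance_rank = as.integer(dominance_rank), rr = rr),
            class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat(sprintf("<gene_params> %s  q=%g  SS=%g  rank=%d  cancers: %s\n",
              x$name, x$allele_freq, x$sensitivity, x$dominance_rank,
              if (length(x$rr)) paste(names(x$rr), collapse = ",") else "none"))
  invisible(x)
}

#' Relative risk of a cancer for a gene carrier at a given age
#'
#' Evaluates the gene's age-piecewise RR; genes with no association with
#' the requested cancer return 1.
#'
#' @param gene a \code{\link{gene_params}} object.
#' @param cancer one of \code{\link{CANCER_TYPES}}.
#' @param age integer age(s) in 0--79.
#' @return positive relative risk(s), vectorised over \code{age}.
#' @export
relative_risk <- function(gene, cancer, age) {
  stopifnot(inherits(gene, "gene_params"))
  cancer <- match.arg(cancer, CANCER_TYPES)
  if (any(age < 0 | age > 79))
    stop("relative_risk: age must lie in 0..79")
  apr <- gene$rr[[cancer]]
  if (is.null(apr)) return(rep(1, length(age)))
  apr$rr[floor(age) + 1L]
}

# full 80-vector of RRs for internal use
rr_vector <- function(gene, cancer) {
  apr <- gene$rr[[cancer]]
  if (is.null(apr)) rep(1, 80L) else apr$rr
}

#' Carrier probability of a single gene
#'
#' Probability of carrying at least one PV allele under Hardy-Weinberg
#' equilibrium: \eqn{2q(1-q) + q^2}.
#'
#' @param x a \code{gene_params} object or allele frequency.
#' @export
carrier_prob <- function(x) {
  q <- if (inherits(x, "gene_params")) x$allele_freq else x
  2 * q * (1 - q) + q^2
}

#' Combined carrier prevalence across a set of genes
#'
#' Probability of carrying a PV allele in at least one of the listed genes,
#' assuming Hardy-Weinberg equilibrium and independence across genes:
#' \eqn{1 - \prod_g (1-q_g)^2}.
#'
#' @param genes list of \code{\link{gene_params}} objects (or a numeric
#'   vector of allele frequencies).
#' @return a fraction.
#' @export
carrier_prevalence <- function(genes) {
  q <- if (is.numeric(genes)) genes
       else vapply(genes, function(g) g$allele_freq, 0)
  if (length(q) == 0L) stop("carrier_prevalence: empty gene set")
  if (any(q < 0 | q >= 1)) stop("carrier_prevalence: invalid allele frequency")
  1 - prod((1 - q)^2)
}

#' Tumour pathology distribution for a gene (or the population)
#'
#' Age-dependent probabilities of an ER-negative tumour given breast-cancer
#' onset at each age, and of triple-negative status given ER-negative.
#' Lookups are linearly interpolated between tabulated ages and extended by
#' nearest neighbour outside the tabulated range.
#'
#' @param label gene symbol or \code{"population"}.
#' @param age tabulated onset ages.
#' @param p_er_neg P(ER- | onset at age).
#' @param p_tn_given_er_neg P(TN | ER-, onset at age).
#' @export
pathology_distribution <- function(label, age, p_er_neg, p_tn_given_er_neg) {
  stopifnot(length(age) == length(p_er_neg),
            length(age) == length(p_tn_given_er_neg))
  if (any(p_er_neg < 0 | p_er_neg > 1) ||
      any(p_tn_given_er_neg < 0 | p_tn_given_er_neg > 1))
    stop(sprintf("pathology_distribution %s: probabilities must lie in [0,1]",
                 label))
  o <- order(age)
  structure(list(label = label, age = age[o], p_er_neg = p_er_neg[o],
                 p_tn_given_er_neg = p_tn_given_er_neg[o]),
            class = "pathology_distribution")
}

path_lookup <- function(dist, age) {
  if (length(dist$age) == 1L)
    return(c(er = dist$p_er_neg, tn = dist$p_tn_given_er_neg))
  c(er = stats::approx(dist$age, dist$p_er_neg, xout = age, rule = 2)$y,
    tn = stats::approx(dist$age, dist$p_tn_given_er_neg, xout = age,
                       rule = 2)$y)
}

#' Probability of an observed pathology category
#'
#' Probability of each of the five ER/TN observation categories given
#' breast-cancer onset at \code{age}, under a gene-specific (or population)
#' pathology distribution. \code{"ER:unknown"} carries no information and
#' returns 1; the three mutually exclusive fully observed categories
#' (ER+, ER-/not-TN, TN) sum to 1.
#'
#' @param dist a \code{\link{pathology_distribution}}.
#' @param category one of \code{\link{PATHOLOGY_CATEGORIES}}.
#' @param age onset age (nearest-neighbour extension outside 20--79).
#' @export
pathology_category_prob <- function(dist, category, age) {
  stopifnot(inherits(dist, "pathology_distribution"))
  if (!category %in% PATHOLOGY_CATEGORIES)
    stop(sprintf("unknown pathology category '%s'", category))
  p <- path_lookup(dist, age)
  switch(category,
         "ER:unknown"     = 1,
         "ER+"            = 1 - p[["er"]],
         "ER-/TN:unknown" = p[["er"]],
         "ER-/not-TN"     = p[["er"]] * (1 - p[["tn"]]),
         "TN"             = p[["er"]] * p[["tn"]])
}

#' Risk category scheme
#'
#' Ordered thresholds on lifetime risk defining exhaustive, disjoint
#' categories; the default schemes follow the familial breast cancer
#' guideline bands (<17\%, 17--30\%, >=30\%) and the corresponding
#' tubo-ovarian bands (<5\%, 5--10\%, >=10\%).
#'
#' @param cancer cancer type the scheme applies to.
#' @param thresholds strictly increasing thresholds on the risk scale [0,1].
#' @param labels category labels, one more than thresholds.
#' @export
risk_category_scheme <- function(cancer, thresholds, labels) {
  stopifnot(length(labels) == length(thresholds) + 1L,
            !is.unsorted(thresholds, strictly = TRUE),
            all(thresholds > 0 & thresholds < 1))
  structure(list(cancer = cancer, thresholds = thresholds, labels = labels),
            class = "risk_category_scheme")
}

default_category_schemes <- function() {
  list(bc = risk_category_scheme("bc", c(0.17, 0.30),
                                 c("near-population", "moderate", "high")),
       eoc = risk_category_scheme("eoc", c(0.05, 0.10),
                                  c("near-population", "moderate", "high")))
}

#' Categorise a lifetime risk
#'
#' Lower category bounds are inclusive: a breast-cancer risk of exactly 30\%
#' is "high", exactly 17\% is "moderate".
#'
#' @param risk risk(s) in [0, 1].
#' @param scheme a \code{\link{risk_category_scheme}}.
#' @return character label(s).
#' @export
categorize_risk <- function(risk, scheme) {
  stopifnot(inherits(scheme, "risk_category_scheme"),
            all(risk >= 0 & risk <= 1))
  scheme$labels[findInterval(risk, scheme$thresholds) + 1L]
}
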