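---
title: "Methods: multifactorial familial breast and ovarian cancer risk"
author: "famrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifactorial familial breast and ovarian cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrisk)
```

## The model

`famrisk` implements a Mendelian multifactorial model of female breast
cancer (BC) and epithelial tubo-ovarian cancer (EOC). An individual's
hazard of cancer at integer age $t$ (ages are discrete, $0 \le t \le 79$,
hazards piecewise-constant on $[t, t+1)$) is

$$\lambda(t) = \lambda_0(t)\; RR_G(t)\; RR_P(t)\; \prod_j RR_{F_j}(t),$$

the product of a baseline hazard, a major-genotype relative risk, a
polygenic relative risk and the relative risks of the modelled
epidemiological risk factors. All components are assumed to act
multiplicatively. The model computes, for a proband embedded in a
pedigree, (i) the posterior probability of carrying a pathogenic variant
(PV) in each modelled susceptibility gene, and (ii) absolute future cancer
risks conditional on family history, genetic tests, tumour pathology of
affected relatives, risk factors and a measured polygenic risk score (PRS).

### Major genes

The BC model carries eight susceptibility genes (BRCA1, BRCA2, PALB2,
CHEK2, ATM, BARD1, RAD51C, RAD51D), the EOC model six (BRCA1, BRCA2,
RAD51D, RAD51C, BRIP1, PALB2). Each gene is parameterised by its
population PV allele frequency $q$, the sensitivity of a clinical
screening test (a carrier tests positive with probability $SS$;
specificity is fixed at 1, so a positive result is taken at face value),
and age-piecewise relative risks per cancer — constants or log-linear
segments $\exp(u + v\,t)$ — for female BC, EOC, male BC, prostate and
pancreatic cancer. The shipped tables in `inst/extdata/` carry the
published point estimates; confidence intervals are not propagated.
Interval bounds are inclusive integer years, and where a published RR is
printed as a single constant without an explicit young-age clause it is
applied over the whole 0–79 range (BC incidence below 20 is negligible, so
this choice is inconsequential).

Genotypes are collapsed: the per-person major-genotype space is
{non-carrier} ∪ {carrier of gene $g$}, with multi-gene carriers assigned
to their highest-dominance gene. Dominance follows the published order for
the long-established genes, with the newly added genes appended in the
order they were introduced. Founder priors assume Hardy–Weinberg
equilibrium and independence across genes (carrier probability
$q(2-q)$ per gene); double carriers have prior mass of order $10^{-6}$,
which motivates the collapse. For transmission, a collapsed carrier state
is expanded into its heterozygote/homozygote composition — so a carrier
parent transmits the PV allele with probability $q/(q(2-q)) = 1/(2-q)$ —
the child's transmitted allele set is formed Mendelianly, and children
carrying two genes are re-collapsed by dominance
(`major_transmission_kernel()`).

### Polygene and PRS

Residual familial aggregation is a normally distributed log-hazard with
age-specific SD $\sigma_P(t)$, discretised on a binomial grid: with $n$
levels (default 7, odd), masses follow $B(n-1, 1/2)$ and level values are
the standardised symmetric grid, giving exact mean 0 and variance 1
(`discretise_polygene()`). Per-age relative risks
$\exp(\sigma_P(t) v_k)$ are renormalised by the discrete population mean,
so the population-mean polygenic RR is exactly 1 at every age.
Parent–offspring transmission uses the hypergeometric convention: each
parent passes half of its $n-1$ dose slots drawn without replacement, so
the child's expectation is the midparent mean and the binomial founder
distribution is stationary across generations
(`polygene_transmission()`; both properties are tested).

$\sigma_P(t)$ is not published in the source material for this model
generation; the shipped configuration uses a constant synthetic value of
1.0, clearly labelled non-canonical. Users with access to the calibrated
age-specific SDs can supply them in the config.

When previously implicit genes are made explicit, their variance is
removed from the polygene so total variance is conserved:
$v_g(t) = p(1-p)\ln^2 RR_g(t)$ with $p$ the carrier probability,
averaged over ages with incidence weights, and
$\sigma_{new}(t) = \sqrt{\sigma_{old}^2(t) - \sum_g v_g(t)}$
(`adjust_polygenic_sd()`; conservation is exact to machine precision).

A measured PRS explains a fraction $\alpha^2$ of the polygenic variance
(0.20 for the BC PRS, 0.05 for the EOC PRS). `condition_on_prs()`
realises the conditional polygene as the shift/scale
$\sigma_P(\alpha z + \sqrt{1-\alpha^2}\,v_k)$ of the discrete levels. In
pedigree computations the same conditioning is applied in observation
form: a recorded z-score contributes a factor
$N(z;\, \alpha v_k,\, 1-\alpha^2)$ to the likelihood of polygene level
$k$, which is the Bayes-consistent counterpart of the shift/scale form
and composes naturally with peeling. The two agree in the continuous
limit; at 7 levels the discrete polygene's implied PRS marginal (a
mixture of normals) deviates from N(0,1) by about $10^{-3}$, which is the
accuracy limit of PRS-averaged quantities.

### Baseline hazards constrained to population incidence

Population incidence is supplied per birth cohort as ages 0–79 rates per
100,000. `build_cohort_incidence()` assembles such tables from
calendar-period registry tables by following each birth year's Lexis
diagonal and averaging over the cohort's birth years — this averaging is
what stabilises rates for rare cancers in small populations; cells beyond
the observed periods borrow the nearest observed period.

Given the joint distribution of risk profiles at birth (major genotype ×
polygene level × risk-factor bins, masses $m_i$, multipliers $RR_i(t)$),
the baseline is constrained sequentially from age 0 so that the
population-averaged hazard among the disease-free equals the population
rate at every age:

$$\lambda_0(t) = \lambda_{pop}(t)\,
  \frac{\sum_i m_i S_i(t)}{\sum_i m_i S_i(t) RR_i(t)},\qquad
  S_i(t) = \exp\!\Big(-\sum_{u<t} \lambda_0(u) RR_i(u)\Big).$$

The constraint identity holds to $10^{-10}$ relative at every age by
construction (tested over randomised profile distributions). Within-year
survival uses the exponential form, which is numerically stable for small
rates; a consequence is a Jensen-type gap of order
$\tfrac12\lambda^2\mathrm{Var}(RR)$ per year between the profile-mixture
cumulative incidence and $1-\exp(-\sum\lambda_{pop})$ — about $10^{-3}$
relative on lifetime risk with the default polygene — so calibration
statements in the package are made against the profile mixture. Competing
mortality is not modelled; risks are pure cumulative cancer incidence.

### Continuous risk factors

Categorical risk factors enter as (mass, RR) tables normalised to
population-mean RR 1. Continuous factors use the adaptive discretisation
with an infinitesimal measured-value bin. For a factor with density
$P(x)$ and risk function $RR(x)$, the range is cut into $n$ bins whose
masses follow $B(n-1, 1/2)$ (boundaries are therefore the density's
quantiles at the cumulative binomial masses, which captures the tails),
with

$$P(i)=\int_{l_i}^{u_i} P(x)\,dx, \qquad
  RR(i)=\frac{1}{P(i)}\int_{l_i}^{u_i} RR(x) P(x)\,dx$$

evaluated by adaptive quadrature at relative tolerance $10^{-10}$
(support truncated at $\mu \pm 8s$, tail mass $<10^{-15}$), and all RRs
rescaled so $\sum_i P(i) RR(i) = 1$. An $(n{+}1)$-th bin of zero width
and zero mass is added at the individual's measured value with
$RR(x)$ (same rescaling): the baseline constraint is unchanged (zero
mass), yet the individual's exact RR is used — no information is lost to
binning while the constraining cost stays fixed. An individual's
percentile is assumed fixed with age.

Adult height ships as the worked example:
$x \sim N(162.81, 6.452^2)$ cm with log-RR per SD $\beta = 0.10130$ for
both cancers. The variance of the population-normalised continuous RR is
$e^{\beta^2}-1 \approx 0.010$.

`choose_n_bins()` selects the bin count: lifetime risk is computed at 100
measured values (percentiles 0.5%–99.5%) for $n = 2, 3, \dots$; each
percentile's sequence is extrapolated to its asymptote with Aitken's
$\Delta^2$ (a Richardson-style estimate, isolated behind one function so
other extrapolants can be substituted), and the smallest $n$ with RMS
relative error below $10^{-4}$ is returned. On the shipped synthetic
incidence this selects $n = 3$; the choice depends on the incidence level,
and steeper real registry tables select larger $n$.

### Pedigree likelihood, pathology and carrier probabilities

A pedigree is a table of individuals with 0 or 2 parents each, validated
for acyclicity, connectedness, birth-order and sex-consistent phenotypes
(consanguinity loops are rejected). Each individual's observation
likelihood given a genotype state multiplies, over the cancers applicable
to their sex: survival to the event/censoring age under
$\lambda_0 RR_{state}$, the hazard at the diagnosis age if affected, the
probability of the observed tumour ER/TN category (five levels: ER
unknown, ER+, ER−/TN unknown, ER−/not TN, TN) under the carried gene's
age-specific pathology distribution (population distribution for
non-carriers and genes without a table), the test-result likelihoods and
the PRS factor. Unknown censoring ages default to current year minus
birth year, capped at 80. Pathology is only modelled for female breast
tumours. Associated cancers (male BC, prostate, pancreatic, and the
other model's primary cancer) contribute through relatives' likelihoods
with their published RRs; their baselines are constrained over major
genotypes only, and the polygene applies to the primary cancer only.

The total likelihood is the exact sum over joint genotype-state
assignments of founder priors × transmission × observation terms,
computed by variable elimination over the pedigree graph
(`peel_likelihood()`), with a greedy smallest-scope elimination order.
An exhaustive enumeration oracle (`enumerate_pedigree_likelihood()`)
validates peeling on every random pedigree small enough to enumerate; the
two agree to $10^{-9}$ relative over 200 seeded random pedigrees. A
configurable cap on factor size turns intractable state spaces into a
clear error suggesting fewer polygene levels. Carrier probabilities are
posterior marginals of the target's collapsed state and sum to 1.

### Absolute risks and reclassification

`future_risk()` weights each state's cumulative incidence
$1-\exp(-\sum_t \lambda_0(t) RR_{state}(t))$ by the peeling posterior;
`lifetime_risk()` specialises to an unaffected 20-year-old followed to
80. Risks are categorised with inclusive lower bounds: BC <17% /
17–30% / ≥30%; EOC <5% / 5–10% / ≥10%.

`risk_distribution()` produces reclassification distributions: for a
fixed carrier status (a test-confirmed PV) and family history ("unknown"
= the proband alone; "mother affected at 50" = a trio whose mother has
the primary cancer at 50 and is censored at a configurable age,
default 55 — the source material does not state this censoring age), it
enumerates the joint population distribution of the requested predictors
(categorical QRF and mammographic-density tables, height over its bins,
PRS on a ≥64-node Gauss–Hermite grid) and computes each combination's
lifetime risk through the full engine. A seeded Monte-Carlo sampler
(`sample_risk_distribution()`) cross-checks the deterministic
enumeration. The shipped QRF and MD tables are synthetic placeholders
(the published distributions live outside the main text), so the shipped
reclassification percentages are illustrative, not the published ones.

## What the synthetic data emulate — and what they do not

The generators in `fixtures` provide everything needed to exercise the
machinery without external downloads:

* `make_incidence()` — calendar tables with constant or log-linear rates.
  The shipped 1985-cohort table uses log-linear-in-age curves chosen to
  give realistic lifetime magnitudes (BC ≈ 11%, EOC ≈ 2%, prostate ≈ 11%,
  pancreas ≈ 0.8%, male BC ≈ 0.08%) but deliberately imitates no real
  registry; absolute risk outputs under it are qualitative.
* `make_pathology_tables()` — logistic ER−-by-age curves with the
  qualitative directions reported for the real distributions: BARD1,
  RAD51C and RAD51D carriers mostly ER-negative with the proportion
  falling with age; CHEK2 and ATM carriers mostly ER-positive with the
  ER+ share rising with age; TN fractions high except CHEK2.
* `make_pedigree()` — random family structures whose genotypes,
  phenotypes, pathology, tests and PRS are simulated *from the model*
  (founder priors, transmission kernels, genotype-specific hazards), so
  parameter-recovery and peeling-vs-enumeration tests are closed-loop.
  Observed heights are drawn independently of phenotype (the simulated
  onsets do not include risk-factor effects), so recovery tests target
  the genetic parameters only.

Passing tests on these fixtures demonstrates the correctness of the
algorithms and the internal calibration of the model; they say nothing
about predictive accuracy on real families, which requires calibrated
national incidence, the published pathology, QRF/MD and polygene tables,
and external validation.

## Numerical choices and degenerate inputs

* Problem sizes: tests peel pedigrees of up to 6 members at 2 genes × 3
  polygene levels against full enumeration (200 seeded replicates);
  parameter recovery uses 10⁴ simulated individuals with carrier
  probability 0.51 and a constant 500/100k hazard from age 20, sized so
  the ±10% recovery band sits ≈2.7 SE from the truth; reclassification
  grids enumerate 5×4×64 predictor combinations.
* Quadrature tolerance $10^{-10}$; bins outside the truncated support get
  zero mass and a midpoint RR so large $n$ remains well-defined.
* Ties and boundaries: piecewise RR segments own their inclusive bounds;
  risk-category lower bounds are inclusive; the pathology lookup
  interpolates linearly inside the tabulated ages and clamps outside.
* Degenerate inputs raise structured errors: allele frequencies outside
  (0, 0.01), masses not summing to 1, variance deficits in the polygene
  adjustment, mutually inconsistent observations (zero likelihood), two
  confirmed PVs under the single-carrier collapse, affected targets in
  risk prediction, cyclic or disconnected pedigrees.
* With a positive test in one gene and untested status in others, each
  gene's test likelihood is evaluated against that gene's allele state
  independently; under the collapse a confirmed PV in two genes is
  inconsistent by construction.

## Known limitations

Point-estimate RRs only; no competing mortality; no contralateral or
male-proband primary risks; no missense-specific risks or intrinsic
subtypes beyond ER/TN; unmeasured risk factors of relatives enter at the
population mean (multiplier 1) rather than as per-bin mixtures; the
carry-forward rule for incidence beyond observed calendar periods is a
deliberate simplification; synthetic defaults for $\sigma_P$, pathology,
QRF/MD and incidence must be replaced with calibrated tables before any
real-world interpretation.
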