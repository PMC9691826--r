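# famrisk

Multifactorial familial breast and ovarian cancer risk prediction in R.

Clinical genetics services increasingly see women carrying pathogenic
variants (PVs) in *moderate-risk* breast cancer genes — BARD1, RAD51C,
RAD51D — and PALB2 carriers asking about ovarian cancer. A useful risk
figure for such a woman cannot come from the gene alone: it depends
jointly on her family history, the tumour pathology of affected
relatives, genetic test results across a panel, lifestyle/anthropometric
risk factors, mammographic density and a polygenic risk score (PRS).
`famrisk` implements the Mendelian multifactorial model family that
combines all of these, for genetic epidemiologists and methodologists who
need a transparent, fully tested, scriptable implementation.

## The model in brief

The hazard of cancer at age *t* for an individual is

    lambda(t) = lambda0(t) * RR_G(t) * RR_P(t) * prod_j RR_Fj(t)

* **Major genes** `RR_G`: eight breast cancer genes (BRCA1, BRCA2, PALB2,
  CHEK2, ATM, BARD1, RAD51C, RAD51D) or six tubo-ovarian genes, each with
  published allele frequency, screening-test sensitivity and
  age-piecewise relative risks; multi-gene carriers collapse to the
  highest-dominance gene.
* **Polygene** `RR_P`: a discretised normal log-hazard (binomial level
  grid, hypergeometric transmission) capturing residual familial
  aggregation; a measured PRS explaining a fraction α² of its variance
  (20% for BC, 5% for EOC) conditions the residual component.
* **Risk factors** `RR_F`: categorical tables, plus a continuous-factor
  scheme that discretises the density into bins with binomial masses
  (Eqs: bin mass `P(i) = ∫ P(x) dx`, bin risk
  `RR(i) = ∫ RR(x)P(x)dx / P(i)`) and appends a zero-mass, zero-width
  bin at the individual's measured value — so the exact measured RR is
  used without inflating the state space. Height ships as the worked
  example: N(162.81, 6.452²) cm, log-RR per SD 0.10130.
* **Baseline** `lambda0`: constrained age by age so the
  population-averaged hazard among the disease-free reproduces
  birth-cohort population incidence exactly.

Pedigree likelihoods are computed by exact peeling (variable elimination)
over collapsed-genotype × polygene states, validated against brute-force
enumeration; carrier probabilities and absolute risks are posterior
summaries of that likelihood. See the methods vignette
(`vignettes/famrisk-methods.Rmd`) for the full account.

## Worked example

A 38-year-old woman, born 1985, whose mother had a triple-negative
breast cancer at 45:

```r
library(famrisk)
m <- default_model("bc")   # shipped gene tables + synthetic incidence

ped <- pedigree(data.frame(
  id      = c("anna", "mother", "father"),
  father  = c("father", "0", "0"),
  mother  = c("mother", "0", "0"),
  sex     = c("F", "F", "M"),
  birth_year = c(1985, 1958, 1956),
  censor_age = c(38, 62, 64),
  bc_age     = c(0, 45, 0),
  pathology  = c(0L, 4L, 0L),   # 4 = mother's tumour was triple-negative
  target     = c(1L, 0L, 0L)))

round(carrier_probabilities(ped, m), 4)
#> noncarrier      BRCA1      BRCA2      PALB2      CHEK2        ATM      BARD1
#>     0.9059     0.0391     0.0108     0.0152     0.0081     0.0051     0.0070
#>     RAD51C     RAD51D
#>     0.0047     0.0041

future_risk(ped, m)
#> <risk_result> bc: risk to age 80 = 18.3%
```

The TN pathology pulls the posterior towards the ER-negative-prone genes
(BRCA1 and, relative to their tiny priors, BARD1/RAD51C/RAD51D), and the
family history roughly doubles her remaining lifetime risk over the
population curve. For a confirmed BARD1 carrier, the reclassification
distribution over questionnaire risk factors, mammographic density and
PRS:

```r
risk_distribution(m, "BARD1", "unknown", c("qrf", "md", "prs"))
#> <risk_distribution> gene BARD1, FH unknown, factors: qrf,md,prs
#>   mean lifetime risk 19.4%; 640 grid points
#>   near-population   45.4%
#>   moderate          39.9%
#>   high              14.7%
```

i.e. a carrier classified "moderate risk" on PV status alone is
substantially reclassified once the other predictors are known. (With the
shipped *synthetic* incidence and risk-factor tables these percentages
are illustrative; supply calibrated national tables for real estimates.)

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","famrisk.R",package="famrisk"))')" \
  carrier-probs --pedigree family.ped
```

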