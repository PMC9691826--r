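Package: famrisk
Title: Multifactorial Familial Breast and Ovarian Cancer Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mendelian cancer risk prediction combining explicit major
    susceptibility genes (BRCA1, BRCA2, PALB2, CHEK2, ATM, BARD1, RAD51C,
    RAD51D, BRIP1) with a discretised polygenic component, polygenic risk
    score conditioning, questionnaire risk factors and a continuous
    risk-factor discretisation scheme with an infinitesimal measured-value
    bin. Computes pedigree likelihoods by exact peeling over collapsed
    major-genotype by polygene states, pathogenic-variant carrier
    probabilities informed by tumour ER/triple-negative pathology, baseline
    incidences constrained to birth-cohort population rates, and absolute
    breast and epithelial tubo-ovarian cancer risks with guideline risk
    categories and reclassification distributions. Includes deterministic
    synthetic-data generators for incidence, pathology and pedigrees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
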