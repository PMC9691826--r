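# famrisk model configuration (schema famrisk-config-1)
#
# Gene table and relative-risk table hold the published major-gene
# parameters. The pathology tables, the polygenic SD, and the QRF/MD
# category distributions are SYNTHETIC fixtures: plausible shapes for
# testing and demonstration, not estimates fit to any population. Do not
# use them for clinical risk assessment.
schema: famrisk-config-1
genes: genes.tsv
relative_risks: relative_risks.tsv
pathology: synthetic_pathology.tsv
polygene:
  n_levels: 7
  sd: 1.0          # synthetic constant polygenic log-RR SD (non-canonical)
  alpha2:
    bc: 0.20       # fraction of polygenic variance explained by the BC PRS
    eoc: 0.05      # fraction explained by the EOC PRS
risk_categories:
  bc:
    thresholds: [0.17, 0.30]
    labels: [near-population, moderate, high]
  eoc:
    thresholds: [0.05, 0.10]
    labels: [near-population, moderate, high]
risk_factors:
  height:
    type: continuous
    mean: 162.81       # cm
    sd: 6.452          # cm
    log_rr_per_sd: 0.10130
    n_bins: 5
  qrf:                 # synthetic questionnaire-risk-factor summary categories
    type: categorical
    masses: [0.15, 0.25, 0.30, 0.20, 0.10]
    rr: [0.55, 0.80, 1.00, 1.35, 1.90]
  md:                  # synthetic BI-RADS-like mammographic density categories
    type: categorical
    masses: [0.10, 0.40, 0.40, 0.10]
    rr: [0.55, 0.85, 1.20, 1.75]
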