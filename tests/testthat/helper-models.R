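# shared fixtures: configs, incidence and small cached models

.helper_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.helper_cache[[key]])) .helper_cache[[key]] <- force(expr)
  .helper_cache[[key]]
}

test_config <- function() cached("config", load_model_config())

synth_incidence <- function() cached("inc", read_cohort_incidence(
  system.file("extdata", "synthetic_incidence_1985.tsv",
              package = "famrisk", mustWork = TRUE)))

# small model for peeling tests: two genes, three polygene levels
tiny_model <- function() cached("tiny", risk_model(
  test_config(), synth_incidence(), cancer = "bc",
  genes = c("BRCA1", "BARD1"), n_polygene_levels = 3L,
  use_risk_factors = FALSE))

# single-gene model: closed-form Bayes checks
bard1_model <- function() cached("bard1", risk_model(
  test_config(), synth_incidence(), cancer = "bc", genes = "BARD1",
  n_polygene_levels = 3L, use_risk_factors = FALSE))

# one-row pedigree builder
singleton <- function(sex = "F", censor = 20, birth = 1985, ...) {
  pedigree(data.frame(id = "p", father = "0", mother = "0", sex = sex,
                      birth_year = birth, censor_age = censor, target = 1L,
                      ..., stringsAsFactors = FALSE))
}
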