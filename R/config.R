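# Model configuration: YAML/TSV hybrid loading, validation and writing.

#' Path to the shipped default model configuration
#' @export
famrisk_default_config <- function() {
  system.file("extdata", "config.yaml", package = "famrisk", mustWork = TRUE)
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Load and validate a model configuration
#'
#' Reads the YAML/TSV hybrid configuration: a gene table (allele frequency,
#' screening sensitivity, dominance rank per model), an age-piecewise
#' relative-risk table, a tumour-pathology table, polygene settings, risk
#' factor definitions and risk-category schemes. All invariants are checked;
#' violations are reported together, naming file, row and field. Genes
#' without a pathology table fall back to the population distribution.
#'
#' @param path path to the YAML configuration (default: shipped config with
#'   the published gene parameters and synthetic fixture tables).
#' @return An object of class \code{model_config} with elements
#'   \code{genes} (per model: named lists of \code{\link{gene_params}}),
#'   \code{pathology}, \code{polygene}, \code{categories},
#'   \code{risk_factors}.
#' @export
load_model_config <- function(path = famrisk_default_config()) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$schema) || !identical(y$schema, "famrisk-config-1"))
    stop(sprintf("unrecognised config schema '%s' (expected famrisk-config-1)",
                 if (is.null(y$schema)) "<missing>" else y$schema))
  dir <- dirname(path)
  errs <- character()
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  gtab <- read_tsv_strict(file.path(dir, y$genes))
  rtab <- read_tsv_strict(file.path(dir, y$relative_risks))
  need <- c("model", "gene", "allele_freq", "sensitivity", "dominance_rank")
  if (!all(need %in% names(gtab)))
    stop(sprintf("%s: missing columns %s", y$genes,
                 paste(setdiff(need, names(gtab)), collapse = ", ")))

  rr_for_gene <- function(gene) {
    seg <- rtab[rtab$gene == gene, , drop = FALSE]
    out <- list()
    for (cn in unique(seg$cancer)) {
      s <- seg[seg$cancer == cn, c("age_lo", "age_hi", "form", "c", "u", "v")]
      out[[cn]] <- tryCatch(age_piecewise_rr(s), error = function(e) {
        note("%s: gene %s cancer %s: %s", y$relative_risks, gene,
             cn, conditionMessage(e))
        NULL
      })
    }
    out[!vapply(out, is.null, TRUE)]
  }

  genes <- list()
  for (m in unique(gtab$model)) {
    sub <- gtab[gtab$model == m, , drop = FALSE]
    if (anyDuplicated(sub$dominance_rank))
      note("%s: model %s: duplicate dominance_rank", y$genes, m)
    gl <- list()
    for (i in seq_len(nrow(sub))) {
      g <- tryCatch(
        gene_params(sub$gene[i], sub$allele_freq[i], sub$sensitivity[i],
                    sub$dominance_rank[i], rr_for_gene(sub$gene[i])),
        error = function(e) {
          note("%s row %d (gene %s): %s", y$genes,
               which(gtab$model == m)[i], sub$gene[i], conditionMessage(e))
          NULL
        })
      if (!is.null(g)) gl[[sub$gene[i]]] <- g
    }
    genes[[m]] <- gl[order(vapply(gl, function(g) g$dominance_rank, 0L))]
  }

  ptab <- read_tsv_strict(file.path(dir, y$pathology))
  pathology <- list()
  for (g in unique(ptab$gene)) {
    s <- ptab[ptab$gene == g, , drop = FALSE]
    pathology[[g]] <- tryCatch(
      pathology_distribution(g, s$age, s$p_er_neg, s$p_tn_given_er_neg),
      error = function(e) {
        note("%s: gene %s: %s", y$pathology, g, conditionMessage(e))
        NULL
      })
  }
  if (is.null(pathology$population))
    note("%s: a 'population' pathology distribution is required", y$pathology)

  pg <- y$polygene
  if (is.null(pg$n_levels) || pg$n_levels < 3 || pg$n_levels %% 2 == 0)
    note("config polygene: n_levels must be an odd integer >= 3")
  if (is.null(pg$sd) || any(pg$sd <= 0))
    note("config polygene: sd must be positive")
  for (cn in names(pg$alpha2))
    if (pg$alpha2[[cn]] < 0 || pg$alpha2[[cn]] > 1)
      note("config polygene: alpha2 for %s outside [0,1]", cn)

  categories <- list()
  for (cn in names(y$risk_categories)) {
    rc <- y$risk_categories[[cn]]
    categories[[cn]] <- tryCatch(
      risk_category_scheme(cn, unlist(rc$thresholds), unlist(rc$labels)),
      error = function(e) {
        note("config risk_categories %s: %s", cn, conditionMessage(e))
        NULL
      })
  }

  rfs <- list()
  for (nm in names(y$risk_factors)) {
    rf <- y$risk_factors[[nm]]
    if (identical(rf$type, "continuous")) {
      rfs[[nm]] <- tryCatch(
        continuous_rf(nm, rf$mean, rf$sd, rf$log_rr_per_sd,
                      n_bins = rf$n_bins),
        error = function(e) {
          note("config risk_factors %s: %s", nm, conditionMessage(e))
          NULL
        })
    } else if (identical(rf$type, "categorical")) {
      m <- unlist(rf$masses); r <- unlist(rf$rr)
      if (abs(sum(m) - 1) > 1e-9)
        note("config risk_factors %s: masses must sum to 1", nm)
      if (any(r <= 0))
        note("config risk_factors %s: rr must be positive", nm)
      if (length(m) != length(r))
        note("config risk_factors %s: masses and rr lengths differ", nm)
      rfs[[nm]] <- list(type = "categorical", name = nm, masses = m, rr = r)
    } else note("config risk_factors %s: unknown type '%s'", nm, rf$type)
  }

  if (length(errs))
    stop(paste(c("invalid model configuration:", errs), collapse = "\n  "))
  structure(list(schema = y$schema, genes = genes, pathology = pathology,
                 polygene = pg, categories = categories, risk_factors = rfs),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  for (m in names(x$genes))
    cat(sprintf("model %-4s: %d genes (%s)\n", m, length(x$genes[[m]]),
                paste(names(x$genes[[m]]), collapse = ", ")))
  cat(sprintf("pathology tables: %s\n", paste(names(x$pathology),
                                              collapse = ", ")))
  cat(sprintf("polygene: %d levels, sd %s\n", x$polygene$n_levels,
              paste(unique(x$polygene$sd), collapse = "/")))
  invisible(x)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a model configuration back to disk
#'
#' Inverse of \code{\link{load_model_config}}: writes the YAML file and the
#' gene, relative-risk and pathology TSVs into \code{dir}. Numeric
#' parameters survive a write/load round trip exactly.
#'
#' @param config a \code{model_config}.
#' @param dir output directory (created if needed).
#' @return invisibly, the path to the written YAML file.
#' @export
write_model_config <- function(config, dir) {
  stopifnot(inherits(config, "model_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  grows <- list(); rrows <- list()
  for (m in names(config$genes)) for (g in config$genes[[m]]) {
    grows[[length(grows) + 1L]] <- data.frame(
      model = m, gene = g$name, allele_freq = fmt_num(g$allele_freq),
      sensitivity = fmt_num(g$sensitivity),
      dominance_rank = g$dominance_rank)
    for (cn in names(g$rr)) {
      key <- paste(g$name, cn)
      if (!is.null(rrows[[key]])) next
      s <- g$rr[[cn]]$segments
      rrows[[key]] <- data.frame(
        gene = g$name, cancer = cn, age_lo = s$age_lo, age_hi = s$age_hi,
        form = s$form, c = fmt_num(s$c), u = fmt_num(s$u), v = fmt_num(s$v))
    }
  }
  wtsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(do.call(rbind, grows), "genes.tsv")
  wtsv(do.call(rbind, unname(rrows)), "relative_risks.tsv")

  prows <- do.call(rbind, lapply(config$pathology, function(p) data.frame(
    gene = p$label, age = p$age, p_er_neg = fmt_num(p$p_er_neg),
    p_tn_given_er_neg = fmt_num(p$p_tn_given_er_neg))))
  wtsv(prows, "pathology.tsv")

  rf_out <- lapply(config$risk_factors, function(rf) {
    if (inherits(rf, "continuous_rf"))
      list(type = "continuous", mean = rf$mean, sd = rf$sd,
           log_rr_per_sd = rf$beta, n_bins = rf$n_bins)
    else list(type = "categorical", masses = rf$masses, rr = rf$rr)
  })
  cat_out <- lapply(config$categories, function(s)
    list(thresholds = s$thresholds, labels = s$labels))
  ypath <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(schema = config$schema, genes = "genes.tsv",
                        relative_risks = "relative_risks.tsv",
                        pathology = "pathology.tsv",
                        polygene = config$polygene,
                        risk_categories = cat_out,
                        risk_factors = rf_out),
                   ypath, precision = 17)
  invisible(ypath)
}
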