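# Pedigree data model and tab-separated file exchange.

PED_HEADER_TAG <- "##famrisk-pedigree 1"

PED_CORE_COLS <- c("id", "father", "mother", "sex", "birth_year",
                   "censor_age", "target")
PED_DX_COLS <- c(bc = "bc_age", eoc = "eoc_age", prostate = "prostate_age",
                 pancreas = "pancreas_age")

#' Construct and validate a pedigree
#'
#' One row per individual. Required columns: \code{id}, \code{father},
#' \code{mother} (0 for founders; individuals have either two parents in
#' the structure or none), \code{sex} ("F"/"M"), \code{birth_year},
#' \code{censor_age} (current age or age at death, capped at 80) and
#' \code{target} (exactly one 1). Optional phenotype columns:
#' \code{bc_age}, \code{eoc_age}, \code{prostate_age}, \code{pancreas_age}
#' (age at diagnosis, 0 = unaffected; a male \code{bc_age} is a male breast
#' cancer), \code{pathology} (0--4: none/ER unknown, ER+, ER-/TN unknown,
#' ER-/not TN, TN), per-gene test columns \code{<GENE>_test}
#' ("0" untested, "N" negative, "P" positive), \code{height} (cm, NA if
#' unmeasured) and \code{prs_z} (PRS z-score, NA if unmeasured).
#'
#' Structural checks: unique ids, both-or-no parents, parental sexes,
#' acyclicity, connectedness, parents born before children, sex-compatible
#' phenotypes, diagnosis ages not after censoring, pathology only with a
#' breast cancer diagnosis.
#'
#' @param df data.frame as described.
#' @param target id of the proband; defaults to the row with
#'   \code{target == 1}, or the only individual in a singleton pedigree.
#' @return object of class \code{pedigree} (the validated data.frame).
#' @export
pedigree <- function(df, target = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  perr <- function(fmt, ...) stop(sprintf(paste0("pedigree: ", fmt), ...))
  for (col in c("id", "father", "mother", "sex", "birth_year", "censor_age"))
    if (is.null(df[[col]])) perr("missing column '%s'", col)
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  if (anyDuplicated(df$id))
    perr("duplicate id '%s'", df$id[duplicated(df$id)][1L])
  if (!all(df$sex %in% c("F", "M"))) perr("sex must be 'F' or 'M'")
  for (col in unname(PED_DX_COLS))
    if (is.null(df[[col]])) df[[col]] <- 0
  if (is.null(df$pathology)) df$pathology <- 0L
  if (is.null(df$height)) df$height <- NA_real_
  if (is.null(df$prs_z)) df$prs_z <- NA_real_
  if (is.null(df$target)) df$target <- 0L
  if (!is.null(target)) {
    if (!target %in% df$id) perr("target '%s' not in pedigree", target)
    df$target <- as.integer(df$id == target)
  }
  if (nrow(df) == 1L && sum(df$target) == 0L) df$target <- 1L
  if (sum(df$target) != 1L) perr("exactly one target individual is required")
  df$censor_age <- pmin(df$censor_age, 80)
  if (any(df$censor_age < 0)) perr("negative censor_age")

  for (i in seq_len(nrow(df))) {
    fa <- df$father[i]; mo <- df$mother[i]
    if ((fa == "0") != (mo == "0"))
      perr("row %d (id %s): individuals need two parents or none", i, df$id[i])
    if (fa != "0") {
      if (!fa %in% df$id)
        perr("row %d (id %s): unknown father '%s'", i, df$id[i], fa)
      if (!mo %in% df$id)
        perr("row %d (id %s): unknown mother '%s'", i, df$id[i], mo)
      if (df$sex[match(fa, df$id)] != "M")
        perr("row %d (id %s): father '%s' is not male", i, df$id[i], fa)
      if (df$sex[match(mo, df$id)] != "F")
        perr("row %d (id %s): mother '%s' is not female", i, df$id[i], mo)
      for (p in c(fa, mo))
        if (df$birth_year[match(p, df$id)] >= df$birth_year[i])
          perr("row %d (id %s): parent '%s' not born before child",
               i, df$id[i], p)
    }
    for (cn in names(PED_DX_COLS)) {
      a <- df[[PED_DX_COLS[[cn]]]][i]
      if (is.na(a)) perr("row %d: NA diagnosis age (use 0)", i)
      if (a > 0) {
        sx <- CANCER_SEX[[if (cn == "bc" && df$sex[i] == "M") "mbc" else cn]]
        if (sx != "MF" && sx != df$sex[i])
          perr("row %d (id %s): %s diagnosis incompatible with sex %s",
               i, df$id[i], cn, df$sex[i])
        if (a > df$censor_age[i])
          perr("row %d (id %s): %s diagnosis after censor age", i, df$id[i], cn)
      }
    }
    if (df$pathology[i] != 0L && df$bc_age[i] == 0)
      perr("row %d (id %s): pathology without a breast cancer diagnosis",
           i, df$id[i])
  }
  if (!all(df$pathology %in% 0:4)) perr("pathology codes must be 0-4")

  # acyclicity via repeated leaf removal, connectedness via flood fill
  alive <- df$id
  repeat {
    # an id is removable if nobody still alive lists it as a parent
    keepf <- df$father[df$id %in% alive]; keepm <- df$mother[df$id %in% alive]
    removable <- setdiff(alive, c(keepf, keepm))
    if (length(removable) == 0L) {
      if (length(alive) > 0L) perr("cyclic parentage involving %s",
                                   paste(alive, collapse = ", "))
      break
    }
    alive <- setdiff(alive, removable)
    if (length(alive) == 0L) break
  }
  if (nrow(df) > 1L) {
    adj <- lapply(seq_len(nrow(df)), function(i) {
      nb <- c(df$father[i], df$mother[i],
              df$id[df$father == df$id[i] | df$mother == df$id[i]])
      setdiff(nb, "0")
    })
    names(adj) <- df$id
    seen <- df$id[1L]; frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < nrow(df))
      perr("pedigree is not connected (e.g. id %s)",
           setdiff(df$id, seen)[1L])
  }
  structure(df, class = c("pedigree", "data.frame"))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals, target %s\n", nrow(x),
              x$id[x$target == 1L]))
  print.data.frame(x, ...)
  invisible(x)
}

ped_target <- function(ped) which(ped$target == 1L)

ped_gene_tests <- function(ped) {
  cols <- grep("_test$", names(ped), value = TRUE)
  stats::setNames(cols, sub("_test$", "", cols))
}

#' Read a pedigree file
#'
#' Tab-separated, one row per individual, first line the version tag
#' \code{##famrisk-pedigree 1}, then a header row with the columns of
#' \code{\link{pedigree}}. Missing values: 0 for parents/diagnoses/tests,
#' NA for height and PRS.
#'
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_pedigree: cannot open '%s': no such file", path))
  first <- readLines(path, n = 1L)
  if (!identical(first, PED_HEADER_TAG))
    stop(sprintf("read_pedigree: missing version tag (expected '%s')",
                 PED_HEADER_TAG))
  hdr <- strsplit(readLines(path, n = 2L)[2L], "\t", fixed = TRUE)[[1L]]
  chr <- c("id", "father", "mother", "sex",
           grep("_test$", hdr, value = TRUE))
  df <- utils::read.delim(path, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE,
                          colClasses = stats::setNames(
                            rep("character", length(chr)), chr))
  for (col in intersect(c("height", "prs_z"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  pedigree(df)
}

#' Write a pedigree file
#' @param ped a \code{\link{pedigree}}.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(PED_HEADER_TAG, con)
  utils::write.table(as.data.frame(ped), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
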