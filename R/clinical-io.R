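#' Read a clinical cohort table
#'
#' One row per patient: overall survival in months from metastatic diagnosis,
#' death indicator, EGFR TKI treatment flag, EGFR mutation class
#' (`sensitizing` or `other`) and the clinical covariates used for adjustment
#' (age, sex, smoking status, surgical resection).  Empty fields are read as
#' missing (`NA`); categorical fields are validated against their
#' vocabularies.
#'
#' @param path CSV file with header
#'   `patient_id,os_months,event,tki_treated,egfr_class,age,sex,smoking_status,surgery`.
#' @return A data.frame of cohort records (possibly 0-row).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    tme_stop(sprintf("read_clinical: no such file '%s'", path))
  need <- c("patient_id", "os_months", "event", "tki_treated", "egfr_class",
            "age", "sex", "smoking_status", "surgery")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    return(as.data.frame(stats::setNames(rep(list(character()), length(need)),
                                         need), stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  miss <- setdiff(need, header)
  if (length(miss))
    tme_stop(sprintf("read_clinical: missing column(s): %s",
                     paste(miss, collapse = ", ")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  chk_binary <- function(col) {
    v <- df[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad))
      tme_stop(sprintf("read_clinical: %s=%s outside {0,1} at data row %d",
                       col, v[bad[1]], bad[1]))
  }
  chk_binary("event")
  chk_binary("tki_treated")
  chk_binary("surgery")
  bad <- which(!is.na(df$os_months) & df$os_months < 0)
  if (length(bad))
    tme_stop(sprintf("read_clinical: negative os_months at data row %d",
                     bad[1]))
  bad <- which(!is.na(df$egfr_class) &
               !(df$egfr_class %in% c("sensitizing", "other")))
  if (length(bad))
    tme_stop(sprintf("read_clinical: unknown egfr_class '%s' at data row %d",
                     df$egfr_class[bad[1]], bad[1]))
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write a clinical cohort table
#'
#' Inverse of [read_clinical()]: CSV, header mandatory, missing values
#' written as empty fields, rows ordered by `patient_id` for deterministic
#' output.
#'
#' @param clinical A cohort data.frame (see [read_clinical()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  need <- c("patient_id", "os_months", "event", "tki_treated", "egfr_class",
            "age", "sex", "smoking_status", "surgery")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    tme_stop(sprintf("write_clinical: missing column(s): %s",
                     paste(miss, collapse = ", ")))
  out <- clinical[order(clinical$patient_id), need, drop = FALSE]
  utils::write.table(out, path, sep = ",", na = "", qmethod = "double",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-by-patient expression matrix
#'
#' Tab-separated file: first column gene symbols, remaining columns one per
#' patient.  Gene symbols are trimmed of surrounding whitespace and matched
#' case-sensitively; duplicate symbols are rejected.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows, patients in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    tme_stop(sprintf("read_expression: no such file '%s'", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2)
    tme_stop("read_expression: need a gene column plus >= 1 patient column")
  genes <- trimws(as.character(df[[1]]))
  if (anyDuplicated(genes))
    tme_stop(sprintf("read_expression: duplicate gene symbol '%s'",
                     genes[anyDuplicated(genes)]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a gene-by-patient expression matrix
#'
#' @param expr Numeric matrix with gene rownames and patient colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line; tab-separated fields are the set name, a
#' description, then the member genes.  Duplicate members within a set are
#' deduplicated (first occurrence kept); duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    tme_stop(sprintf("read_gmt: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 3)
      tme_stop(sprintf("read_gmt: line %d has %d field(s), need >= 3",
                       i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets))
      tme_stop(sprintf("read_gmt: duplicate set name '%s' at line %d", nm, i))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      tme_stop(sprintf("read_gmt: set '%s' at line %d is empty", nm, i))
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param path Output file path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    d <- if (nm %in% names(descriptions)) descriptions[[nm]] else "na"
    if (is.na(d) || !nzchar(d)) d <- "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
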