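#' Read a methylation matrix from disk
#'
#' Reads a delimited-text (or optionally RDS-serialized) labelled numeric
#' grid, canonicalizes its orientation with [orient_matrix()] and detects
#' its value scale with [detect_value_scale()]. Both samples-as-rows and
#' CpGs-as-rows layouts are accepted; the CSV dialect expects the first
#' column to carry the row labels and the header the column labels. Empty
#' cells and the literal token `NA` are treated as missing.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (native; any delimiter `data.table::fread` can
#'   sniff) or `"rds"` (an R-serialized matrix or data frame, the dialect
#'   the original web platform used).
#' @param qc Optional [qc_report()]; orientation and scale detection are
#'   logged.
#' @return A `methyl_matrix` with samples as rows.
#' @export
read_methylation_matrix <- function(path, dialect = c("csv", "rds"),
                                    qc = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "rds") {
    obj <- readRDS(path)
    if (is.data.frame(obj)) obj <- as.matrix(obj)
    if (!is.matrix(obj))
      stop("RDS file does not contain a matrix or data frame: ", path,
           call. = FALSE)
    values <- obj
    storage.mode(values) <- "double"
  } else {
    dt <- tryCatch(
      data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                        data.table = TRUE, keepLeadingZeros = TRUE),
      error = function(e) stop("cannot parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (ncol(dt) < 2L)
      stop("matrix file must have a label column plus at least one value ",
           "column: ", path, call. = FALSE)
    labels <- as.character(dt[[1L]])
    body <- dt[, -1L, drop = FALSE]
    bad <- names(body)[!vapply(body, is.numeric, logical(1))]
    if (length(bad))
      stop("non-numeric values in column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    values <- as.matrix(body)
    rownames(values) <- labels
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    dups <- c(rownames(values)[duplicated(rownames(values))],
              colnames(values)[duplicated(colnames(values))])
    stop("duplicate axis labels: ", paste(unique(dups), collapse = ", "),
         call. = FALSE)
  }
  m <- orient_matrix(values, qc = qc)
  qc_add(qc, "scale",
         sprintf("%s values detected",
                 if (m$scale == "beta") "beta" else "M"))
  m
}

#' Write a methylation matrix to CSV
#'
#' Writes samples as rows with a leading `ID` label column, the layout
#' [read_methylation_matrix()] reads back without transposition. Missing
#' values are written as the literal token `NA`.
#'
#' @param m A `methyl_matrix`.
#' @param path Output path.
#' @param cpgs_as_rows Write the transposed (CpGs-as-rows) layout instead,
#'   the orientation recommended for uploads to the original platform.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(m, path, cpgs_as_rows = FALSE) {
  stopifnot(inherits(m, "methyl_matrix"))
  values <- if (cpgs_as_rows) t(m$values) else m$values
  dt <- data.table::data.table(ID = rownames(values))
  for (j in colnames(values)) dt[[j]] <- values[, j]
  data.table::fwrite(dt, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample annotation (SexAgeInfo) file
#'
#' The annotation file carries three columns with exact header names `ID`,
#' `Sex` and `Age`. Sex must be written `Male`, `Female` or `NA`; age is
#' chronological age in years and may be missing per sample.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `sample_annotations` with columns `ID`
#'   (character), `Sex` (character, `NA` for unknown) and `Age` (numeric
#'   years, `NA` allowed).
#' @export
read_sample_annotations <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  missing_cols <- setdiff(c("ID", "Sex", "Age"), names(dt))
  if (length(missing_cols))
    stop("annotation file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ann <- data.frame(ID = as.character(dt$ID),
                    Sex = as.character(dt$Sex),
                    Age = suppressWarnings(as.numeric(dt$Age)),
                    stringsAsFactors = FALSE)
  bad_sex <- setdiff(unique(ann$Sex[!is.na(ann$Sex)]), c("Male", "Female"))
  if (length(bad_sex))
    stop("sex must be written 'Male', 'Female' or 'NA'; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$ID))
    stop("duplicate sample ids in annotation file", call. = FALSE)
  if (any(ann$Age < 0, na.rm = TRUE))
    stop("negative ages in annotation file", call. = FALSE)
  class(ann) <- c("sample_annotations", "data.frame")
  ann
}

#' Read a binary phenotype (case/control) file
#'
#' First column is `ID`; every remaining column is a binary phenotype with
#' individuals coded `0` for controls and `1` for cases; missing status is
#' allowed.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `phenotype_table`: `ID` plus one 0/1/`NA`
#'   column per phenotype.
#' @export
read_phenotype_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  if (names(dt)[1L] != "ID")
    stop("first column of the phenotype file must be 'ID'", call. = FALSE)
  if (ncol(dt) < 2L)
    stop("phenotype file has no phenotype columns beyond 'ID'",
         call. = FALSE)
  pheno <- dt
  pheno$ID <- as.character(pheno$ID)
  for (j in names(pheno)[-1L]) {
    raw <- pheno[[j]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & (is.na(v) | !(v %in% c(0, 1)))
    if (any(bad))
      stop("phenotype '", j, "' must be coded 0 (control) or 1 (case); ",
           "found: ", paste(unique(raw[bad]), collapse = ", "),
           call. = FALSE)
    pheno[[j]] <- as.integer(v)
  }
  if (anyDuplicated(pheno$ID))
    stop("duplicate sample ids in phenotype file", call. = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}

#' Read a probe-truncation list
#'
#' A single-column CSV of CpG ids (header optional as long as the column's
#' entries are probe ids) naming the probes a score calculation requires.
#'
#' @param path Path to the file.
#' @return Character vector of CpG ids.
#' @export
read_cpg_list <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  ids <- as.character(dt[[1L]])
  # fread demotes a cg-id header to a data row only if told; recover it
  h <- names(dt)[1L]
  if (is_cpg_id(h)) ids <- c(h, ids)
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) stop("empty CpG list: ", path, call. = FALSE)
  ids
}
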