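#' Quality-control report
#'
#' A `qc_report` is an append-only log of the automated processing steps
#' applied to an uploaded methylation matrix: whether it was transposed,
#' whether M values were converted to beta values, how many cells were
#' mean-imputed, how many probes were filled from a reference panel, and so
#' on. It mirrors the printed report a user of the original web platform
#' sees after score calculation.
#'
#' The report is a mutable environment so that pipeline functions can append
#' records without threading the log through every return value. Records are
#' `(step, action, count)` triples; `count` is `NA` for steps that have no
#' natural count.
#'
#' @return An empty `qc_report` object.
#' @examples
#' qc <- qc_report()
#' qc_add(qc, "orientation", "matrix transposed so samples are rows")
#' qc_records(qc)
#' @export
qc_report <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- data.frame(
    step = character(), action = character(), count = double(),
    stringsAsFactors = FALSE
  )
  class(env) <- "qc_report"
  env
}

#' Append a record to a QC report
#'
#' @param qc A [qc_report()] object, or `NULL` (in which case nothing is
#'   logged; every pipeline function accepts an optional report).
#' @param step Short machine-readable step label, e.g. `"impute"`.
#' @param action Human-readable description of what was done.
#' @param count Optional count associated with the action (cells imputed,
#'   probes filled, ...).
#' @return `qc`, invisibly.
#' @export
qc_add <- function(qc, step, action, count = NA_real_) {
  if (is.null(qc)) return(invisible(NULL))
  stopifnot(inherits(qc, "qc_report"))
  qc$records <- rbind(
    qc$records,
    data.frame(step = step, action = action, count = as.double(count),
               stringsAsFactors = FALSE)
  )
  invisible(qc)
}

#' Retrieve QC report records
#'
#' @param qc A [qc_report()] object.
#' @return A data frame with columns `step`, `action`, `count`.
#' @export
qc_records <- function(qc) {
  stopifnot(inherits(qc, "qc_report"))
  qc$records
}

#' @export
format.qc_report <- function(x, ...) {
  rec <- qc_records(x)
  if (nrow(rec) == 0L) return("QC report: no actions recorded")
  lines <- vapply(seq_len(nrow(rec)), function(i) {
    cnt <- if (is.na(rec$count[i])) "" else sprintf(" [n=%s]", format(rec$count[i]))
    sprintf("[%s] %s%s", rec$step[i], rec$action[i], cnt)
  }, character(1))
  c("QC report:", lines)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a QC report to a plain-text file
#'
#' @param qc A [qc_report()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  writeLines(format(qc), path)
  invisible(path)
}
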