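#' Methylation matrix container
#'
#' A `methyl_matrix` holds a dense samples-by-CpGs grid of methylation
#' levels together with its declared value scale. Beta values are
#' proportions methylated in \[0, 1\] (a beta of 0.5 means half of the DNA
#' molecules in the sample are methylated at that site); M values are the
#' unbounded logit-type transform `M = log2(beta / (1 - beta))`.
#'
#' Rows are samples, columns are CpG probes identified by Illumina-style
#' `"cg"`-prefixed ids. Use [orient_matrix()] to canonicalize a matrix whose
#' axes are the other way around, as uploads with CpGs as rows are equally
#' common.
#'
#' @param values Numeric matrix with unique row names (sample ids) and
#'   unique column names (CpG ids). `NA` entries are allowed.
#' @param scale `"beta"` or `"m_value"`.
#' @param orientation_log Character vector of notes describing any
#'   transposition applied during canonicalization.
#' @return A `methyl_matrix` object.
#' @examples
#' m <- methyl_matrix(
#'   matrix(c(0.2, 0.8, 0.5, 0.4), 2, 2,
#'          dimnames = list(c("S1", "S2"), c("cg01", "cg02"))),
#'   scale = "beta"
#' )
#' cpg_ids(m)
#' @export
methyl_matrix <- function(values, scale = c("beta", "m_value"),
                          orientation_log = character()) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0 ||
      is.null(colnames(values)) && ncol(values) > 0)
    stop("`values` must have both row (sample) and column (CpG) names",
         call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate CpG ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("beta-scale matrix contains values outside [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, scale = scale,
         orientation_log = as.character(orientation_log)),
    class = "methyl_matrix"
  )
}

#' @rdname methyl_matrix
#' @param m A `methyl_matrix`.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname methyl_matrix
#' @export
cpg_ids <- function(m) colnames(m$values)

#' @export
dim.methyl_matrix <- function(x) dim(x$values)

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d samples x %d CpGs, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0) cat(sprintf("  missing cells: %d\n", n_miss))
  if (length(x$orientation_log))
    cat(paste0("  ", x$orientation_log, collapse = "\n"), "\n")
  invisible(x)
}

# Illumina-style probe id: "cg" followed by digits.
is_cpg_id <- function(x) grepl("^cg[0-9]+$", x)

# Fraction of labels on an axis that look like CpG probe ids.
cpg_axis_fraction <- function(labels) {
  if (length(labels) == 0L) return(0)
  mean(is_cpg_id(labels))
}

#' Canonicalize matrix orientation
#'
#' Uploads are accepted with samples as rows or as columns. The CpG axis is
#' identified by a majority vote: an axis whose labels are at least 90%
#' Illumina-style probe ids (`^cg[0-9]+$`) is taken to be the CpG axis and
#' becomes the column axis. The operation is idempotent.
#'
#' @param m A `methyl_matrix`, or a labelled numeric matrix (which is
#'   wrapped with the scale detected by [detect_value_scale()]).
#' @param qc Optional [qc_report()] to note any transposition.
#' @return A `methyl_matrix` with CpGs as columns.
#' @export
orient_matrix <- function(m, qc = NULL) {
  if (inherits(m, "methyl_matrix")) {
    values <- m$values
    scale <- m$scale
    log0 <- m$orientation_log
  } else {
    values <- m
    scale <- NULL
    log0 <- character()
  }
  row_frac <- cpg_axis_fraction(rownames(values))
  col_frac <- cpg_axis_fraction(colnames(values))
  thr <- 0.9
  if (row_frac >= thr && col_frac >= thr)
    stop("ambiguous orientation: both row labels (", round(100 * row_frac),
         "% CpG-like) and column labels (", round(100 * col_frac),
         "% CpG-like) match the CpG id pattern", call. = FALSE)
  if (row_frac < thr && col_frac < thr)
    stop("ambiguous orientation: neither row labels (", round(100 * row_frac),
         "% CpG-like) nor column labels (", round(100 * col_frac),
         "% CpG-like) match the CpG id pattern", call. = FALSE)
  if (row_frac >= thr) {
    values <- t(values)
    note <- "matrix transposed so that samples are rows and CpGs are columns"
    log0 <- c(log0, note)
    qc_add(qc, "orientation", note)
  } else {
    qc_add(qc, "orientation", "samples already on rows; no transposition needed")
  }
  if (is.null(scale)) scale <- detect_value_scale(values)
  methyl_matrix(values, scale = scale, orientation_log = log0)
}

#' Detect whether a matrix holds beta or M values
#'
#' Beta values are bounded proportions; M values are unbounded. The
#' detection rule is: any non-missing value outside \[0, 1\] means the
#' matrix holds M values, otherwise beta values.
#'
#' @param m A `methyl_matrix` or numeric matrix with at least one
#'   non-missing value.
#' @return `"beta"` or `"m_value"`.
#' @export
detect_value_scale <- function(m) {
  values <- if (inherits(m, "methyl_matrix")) m$values else m
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("cannot detect value scale: all values are missing", call. = FALSE)
  if (min(v) < 0 || max(v) > 1) "m_value" else "beta"
}

#' Subset a matrix to the probes a score calculator needs
#'
#' Mirrors the truncation list distributed with the platform: keeps only
#' the columns named in `required`, preserving the matrix's original column
#' order. An empty intersection is a warning, not an error — downstream
#' reference fill can still supply every probe a model needs.
#'
#' @param m A `methyl_matrix`.
#' @param required Character vector of CpG ids to retain.
#' @param qc Optional [qc_report()].
#' @return A `methyl_matrix` with columns restricted to `required`.
#' @export
truncate_to_required_cpgs <- function(m, required, qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"))
  if (length(required) == 0L)
    stop("`required` CpG list is empty", call. = FALSE)
  keep <- cpg_ids(m) %in% required
  if (!any(keep))
    warning("no uploaded CpGs are in the required list; ",
            "returning a 0-column matrix", call. = FALSE)
  out <- m$values[, keep, drop = FALSE]
  qc_add(qc, "truncate",
         sprintf("matrix truncated from %d to %d CpGs on the required list",
                 ncol(m$values), sum(keep)),
         count = sum(keep))
  methyl_matrix(out, scale = m$scale, orientation_log = m$orientation_log)
}
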