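#' Convert M values to beta values
#'
#' Applies the standard logistic relation `beta = 2^M / (2^M + 1)`, the
#' inverse of `M = log2(beta / (1 - beta))`. Missing entries stay missing.
#' Calling this on a matrix already on the beta scale is a logged no-op,
#' matching the tolerant behaviour of the original platform.
#'
#' @param m A `methyl_matrix`.
#' @param qc Optional [qc_report()].
#' @return A `methyl_matrix` on the beta scale.
#' @examples
#' m2b <- function(v) 2^v / (2^v + 1)
#' m2b(0)   # 0.5
#' m2b(1)   # 2/3
#' @export
m_to_beta <- function(m, qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"))
  if (m$scale == "beta") {
    qc_add(qc, "convert", "values already on the beta scale; no conversion")
    return(m)
  }
  values <- 2^m$values / (2^m$values + 1)
  qc_add(qc, "convert", "M values were uploaded and converted to beta values",
         count = sum(!is.na(values)))
  methyl_matrix(values, scale = "beta", orientation_log = m$orientation_log)
}

#' Convert beta values to M values
#'
#' The inverse map `M = log2(beta / (1 - beta))`, exposed mainly so that
#' round-trip checks and M-value fixtures can be built. Betas of exactly 0
#' or 1 map to infinite M values.
#'
#' @param m A `methyl_matrix` on the beta scale.
#' @return A `methyl_matrix` on the M-value scale.
#' @export
beta_to_m <- function(m) {
  stopifnot(inherits(m, "methyl_matrix"), m$scale == "beta")
  values <- log2(m$values / (1 - m$values))
  structure(list(values = values, scale = "m_value",
                 orientation_log = m$orientation_log),
            class = "methyl_matrix")
}

#' Clip out-of-range beta values
#'
#' Normalization pipelines occasionally emit beta values slightly outside
#' \[0, 1\] (e.g. -0.001). When a matrix is declared beta-scale by the
#' caller, such values are clipped to the unit interval with a QC warning
#' rather than rejected.
#'
#' @param values Numeric matrix.
#' @param qc Optional [qc_report()].
#' @return The clipped matrix.
#' @export
clip_beta_values <- function(values, qc = NULL) {
  out_of_range <- !is.na(values) & (values < 0 | values > 1)
  if (any(out_of_range)) {
    values[!is.na(values) & values < 0] <- 0
    values[!is.na(values) & values > 1] <- 1
    qc_add(qc, "clip",
           "beta values outside [0, 1] clipped to the unit interval",
           count = sum(out_of_range))
  }
  values
}

#' Mean-impute missing methylation values
#'
#' Every missing entry at a CpG is replaced by the mean of the non-missing
#' values at that CpG across the uploaded samples; observed entries are
#' untouched. A probe with no observed values at all is left missing here —
#' it is the reference-fill step's job ([fill_missing_cpgs()]) to supply
#' probes the upload cannot inform.
#'
#' @param m A `methyl_matrix` on the beta scale.
#' @param qc Optional [qc_report()].
#' @return A `methyl_matrix` with no missing cells at partially observed
#'   probes.
#' @export
impute_missing_values <- function(m, qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"))
  if (m$scale != "beta")
    stop("imputation runs on the beta scale; convert with m_to_beta() first",
         call. = FALSE)
  values <- m$values
  na_idx <- is.na(values)
  n_imputed <- 0L
  if (any(na_idx)) {
    col_means <- colMeans(values, na.rm = TRUE)  # NaN for all-missing probes
    fully_missing <- !is.finite(col_means)
    for (j in which(colSums(na_idx) > 0L & !fully_missing)) {
      miss <- na_idx[, j]
      values[miss, j] <- col_means[j]
      n_imputed <- n_imputed + sum(miss)
    }
    if (any(fully_missing))
      qc_add(qc, "impute",
             sprintf("%d probe(s) had no observed values and were left missing",
                     sum(fully_missing)),
             count = sum(fully_missing))
  }
  qc_add(qc, "impute",
         sprintf("%d missing value(s) mean-imputed across input individuals",
                 n_imputed),
         count = n_imputed)
  methyl_matrix(values, scale = "beta", orientation_log = m$orientation_log)
}

#' Fill probes absent from the upload with reference means
#'
#' A predictor may need CpG sites the uploaded array did not measure. For
#' each such probe, every individual receives the reference-cohort mean
#' beta value — a constant that shifts every score by the same amount,
#' bringing scores closer to the reference sample while letting every
#' weight in the model be used.
#'
#' @param m A `methyl_matrix` on the beta scale.
#' @param model_cpgs Character vector of CpG ids the predictor(s) require.
#' @param panel A [reference_panel()] whose `cpg_means` cover every
#'   required probe absent from `m`.
#' @param qc Optional [qc_report()].
#' @return A `methyl_matrix` containing every probe in `model_cpgs`.
#' @export
fill_missing_cpgs <- function(m, model_cpgs, panel, qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"), inherits(panel, "reference_panel"))
  if (m$scale != "beta")
    stop("reference fill runs on the beta scale; convert with m_to_beta() first",
         call. = FALSE)
  absent <- setdiff(model_cpgs, cpg_ids(m))
  if (length(absent) == 0L) {
    qc_add(qc, "fill", "all required CpGs present in the upload; none filled",
           count = 0)
    return(m)
  }
  uncovered <- setdiff(absent, names(panel$cpg_means))
  if (length(uncovered))
    stop("required CpG(s) absent from both the upload and the reference ",
         "panel: ", paste(uncovered, collapse = ", "), call. = FALSE)
  fill <- matrix(rep(panel$cpg_means[absent], each = nrow(m$values)),
                 nrow = nrow(m$values),
                 dimnames = list(sample_ids(m), absent))
  qc_add(qc, "fill",
         sprintf("%d CpG(s) absent from the upload filled with reference mean beta values",
                 length(absent)),
         count = length(absent))
  methyl_matrix(cbind(m$values, fill), scale = m$scale,
                orientation_log = m$orientation_log)
}
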