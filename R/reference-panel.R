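#' Reference panel
#'
#' External reference-cohort summaries used in two places: per-CpG mean
#' beta values fill probes that a predictor needs but the upload lacks, and
#' optional per-individual reference scores and measured phenotypes back
#' the comparison panels (inter-predictor correlations in the reference
#' cohort, and predicted-versus-measured trait correlations under age/sex
#' subsetting).
#'
#' @param cpg_means Named numeric vector: CpG id to mean beta in \[0, 1\].
#' @param reference_scores Optional data frame with columns `Age`, `Sex`
#'   and one predicted-score column per trait, one row per reference
#'   individual.
#' @param reference_phenotypes Optional data frame, row-aligned with
#'   `reference_scores`, holding the measured phenotype values for the same
#'   traits (columns named by trait; traits without measurements simply
#'   absent).
#' @param provenance Free-text label describing the reference cohort.
#' @return A `reference_panel` object.
#' @export
reference_panel <- function(cpg_means, reference_scores = NULL,
                            reference_phenotypes = NULL,
                            provenance = "synthetic reference cohort") {
  cpg_means <- unlist(cpg_means)
  if (is.null(names(cpg_means)) || anyNA(names(cpg_means)))
    stop("`cpg_means` must be a named vector keyed by CpG id", call. = FALSE)
  if (any(cpg_means < 0 | cpg_means > 1, na.rm = TRUE))
    stop("reference mean beta values must lie in [0, 1]", call. = FALSE)
  if (!is.null(reference_phenotypes) && !is.null(reference_scores) &&
      nrow(reference_phenotypes) != nrow(reference_scores))
    stop("reference score and phenotype tables must be row-aligned",
         call. = FALSE)
  structure(
    list(cpg_means = cpg_means,
         reference_scores = reference_scores,
         reference_phenotypes = reference_phenotypes,
         provenance = provenance),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel (%s): %d CpG means", x$provenance,
              length(x$cpg_means)))
  if (!is.null(x$reference_scores))
    cat(sprintf(", %d reference individuals", nrow(x$reference_scores)))
  cat("\n")
  invisible(x)
}

#' Read a reference panel from disk
#'
#' The panel's probe means live in a CSV with header `CpG,MeanBeta`.
#' Reference scores and measured phenotypes are optional companion CSVs
#' (`Age,Sex,<trait columns>`), row-aligned with each other.
#'
#' @param means_path CSV with columns `CpG`, `MeanBeta`.
#' @param scores_path,phenotypes_path Optional companion CSVs.
#' @param provenance Label stored on the panel.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(means_path, scores_path = NULL,
                                 phenotypes_path = NULL,
                                 provenance = basename(means_path)) {
  dt <- data.table::fread(means_path, header = TRUE, data.table = FALSE)
  if (!all(c("CpG", "MeanBeta") %in% names(dt)))
    stop("reference panel file must have columns CpG,MeanBeta",
         call. = FALSE)
  means <- stats::setNames(as.numeric(dt$MeanBeta), as.character(dt$CpG))
  read_ref <- function(p) {
    if (is.null(p)) return(NULL)
    data.table::fread(p, header = TRUE, na.strings = c("", "NA"),
                      data.table = FALSE)
  }
  reference_panel(means,
                 reference_scores = read_ref(scores_path),
                 reference_phenotypes = read_ref(phenotypes_path),
                 provenance = provenance)
}

#' Write a reference panel's probe means (and optional companions) to disk
#'
#' @param panel A [reference_panel()].
#' @param means_path Output CSV for the probe means.
#' @param scores_path,phenotypes_path Optional output CSVs for the
#'   reference score and phenotype tables.
#' @return `means_path`, invisibly.
#' @export
write_reference_panel <- function(panel, means_path, scores_path = NULL,
                                  phenotypes_path = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  data.table::fwrite(
    data.table::data.table(CpG = names(panel$cpg_means),
                           MeanBeta = unname(panel$cpg_means)),
    means_path, na = "NA", quote = FALSE)
  if (!is.null(scores_path) && !is.null(panel$reference_scores))
    data.table::fwrite(panel$reference_scores, scores_path, na = "NA",
                       quote = FALSE)
  if (!is.null(phenotypes_path) && !is.null(panel$reference_phenotypes))
    data.table::fwrite(panel$reference_phenotypes, phenotypes_path,
                       na = "NA", quote = FALSE)
  invisible(means_path)
}
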