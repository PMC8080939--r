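#' Cohort filter
#'
#' A filter restricting a score table to an age range (inclusive, in
#' years), a sex, and optionally case or control status for one binary
#' phenotype. Age filtering uses each sample's effective age:
#' chronological age when present, the epigenetic-age prediction for
#' samples without age data — the same fallback the original platform
#' applies to its age slider.
#'
#' @param age_range Numeric `c(low, high)`, inclusive; default unbounded.
#' @param sex `"Male"`, `"Female"` or `"both"`. When a specific sex is
#'   requested, samples with unknown sex are excluded.
#' @param status_phenotype Optional phenotype name from the joined
#'   phenotype table.
#' @param status `"cases"`, `"controls"` or `"both"`.
#' @return A `cohort_filter` object.
#' @export
cohort_filter <- function(age_range = c(-Inf, Inf),
                          sex = c("both", "Male", "Female"),
                          status_phenotype = NULL,
                          status = c("both", "cases", "controls")) {
  sex <- match.arg(sex)
  status <- match.arg(status)
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
  structure(list(age_range = as.numeric(age_range), sex = sex,
                 status_phenotype = status_phenotype, status = status),
            class = "cohort_filter")
}

#' Subset a score table with a cohort filter
#'
#' @param t A [score_table()].
#' @param filter A [cohort_filter()].
#' @param phenotypes Optional [read_phenotype_table()] data frame, required
#'   when the filter restricts by case/control status. Samples with missing
#'   status are excluded from both cases and controls.
#' @return The filtered [score_table()]; possibly 0 rows.
#' @export
subset_cohort <- function(t, filter = cohort_filter(), phenotypes = NULL) {
  stopifnot(inherits(t, "score_table"), inherits(filter, "cohort_filter"))
  keep <- rep(TRUE, nrow(t))
  if (any(is.finite(filter$age_range))) {
    age <- effective_age(t)
    keep <- keep & !is.na(age) & age >= filter$age_range[1] &
      age <= filter$age_range[2]
  }
  if (filter$sex != "both") {
    sex <- if ("Sex" %in% names(t)) t$Sex else rep(NA_character_, nrow(t))
    keep <- keep & !is.na(sex) & sex == filter$sex
  }
  if (filter$status != "both") {
    ph <- filter$status_phenotype
    if (is.null(phenotypes) || is.null(ph))
      stop("status filtering requires a phenotype table and a phenotype name",
           call. = FALSE)
    if (!ph %in% names(phenotypes))
      stop("phenotype '", ph, "' not found; available: ",
           paste(setdiff(names(phenotypes), "ID"), collapse = ", "),
           call. = FALSE)
    status <- phenotypes[[ph]][match(t$ID, phenotypes$ID)]
    wanted <- if (filter$status == "cases") 1L else 0L
    keep <- keep & !is.na(status) & status == wanted
  }
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  score_table(out, traits = score_traits(t), years_traits = years_traits(t))
}

# Mid-rank percentile: p = 100 * (rank - 0.5) / n with average ranks for
# ties. Bounded away from 0 and 100; a single observation sits at 50.
midrank_percentile <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Percentile ranks within the displayed cohort
#'
#' For every trait except those reported in years, each sample's score is
#' replaced by its mid-rank percentile (0-100) within the table. Years-unit
#' traits (the age clock) and the chronological `Age` annotation pass
#' through unchanged. Percentiles always describe the table given — rank
#' after subsetting to match the platform's dynamically updating panels.
#'
#' @param t A [score_table()] with at least one sample.
#' @return A data frame shaped like `t` with trait columns on the
#'   percentile scale (years-unit traits untouched).
#' @export
percentile_ranks <- function(t) {
  stopifnot(inherits(t, "score_table"))
  if (nrow(t) == 0L)
    stop("cannot compute percentile ranks for an empty table", call. = FALSE)
  out <- as.data.frame(t)
  for (tr in setdiff(score_traits(t), years_traits(t)))
    out[[tr]] <- midrank_percentile(out[[tr]])
  out
}

#' Percentile profile for one individual
#'
#' The selected sample's percentile rank (or years, for the age clock) for
#' each requested trait, computed within the table supplied — subset the
#' table first to profile against a restricted cohort.
#'
#' @param t A [score_table()].
#' @param sample_id Sample id present in `t`.
#' @param traits Traits to report; default all.
#' @return Named numeric vector, one entry per trait.
#' @export
individual_profile <- function(t, sample_id, traits = score_traits(t)) {
  stopifnot(inherits(t, "score_table"))
  if (!sample_id %in% t$ID)
    stop("sample '", sample_id, "' not found in the score table",
         call. = FALSE)
  unknown <- setdiff(traits, score_traits(t))
  if (length(unknown))
    stop("unknown trait(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(score_traits(t), collapse = ", "),
         call. = FALSE)
  ranks <- percentile_ranks(t)
  row <- ranks[ranks$ID == sample_id, traits, drop = FALSE]
  stats::setNames(as.numeric(row[1L, ]), traits)
}

#' Case percentile summary per trait
#'
#' Percentile ranks are computed on the full table given (cases and
#' controls together), then summarized over the cases: median, first and
#' third quartile (linear interpolation between order statistics), with
#' case and control counts. Samples with missing status are excluded.
#'
#' @param t A [score_table()].
#' @param phenotypes A [read_phenotype_table()] data frame.
#' @param phenotype Phenotype (column) name to stratify on.
#' @param traits Traits to summarize; defaults to all non-years traits.
#' @return A data frame of class `case_control_summary` with columns
#'   `trait`, `median`, `q1`, `q3`, `n_cases`, `n_controls`. Zero cases
#'   yield an empty summary with a warning.
#' @export
case_control_summary <- function(t, phenotypes, phenotype,
                                 traits = setdiff(score_traits(t),
                                                  years_traits(t))) {
  stopifnot(inherits(t, "score_table"))
  if (!phenotype %in% names(phenotypes))
    stop("phenotype '", phenotype, "' not found; available: ",
         paste(setdiff(names(phenotypes), "ID"), collapse = ", "),
         call. = FALSE)
  status <- phenotypes[[phenotype]][match(t$ID, phenotypes$ID)]
  is_case <- !is.na(status) & status == 1L
  is_ctrl <- !is.na(status) & status == 0L
  empty <- data.frame(trait = character(), median = double(), q1 = double(),
                      q3 = double(), n_cases = integer(),
                      n_controls = integer(), stringsAsFactors = FALSE)
  if (!any(is_case)) {
    warning("no cases for phenotype '", phenotype, "'; empty summary",
            call. = FALSE)
    class(empty) <- c("case_control_summary", "data.frame")
    return(empty)
  }
  ranks <- percentile_ranks(t)
  rows <- lapply(traits, function(tr) {
    p <- ranks[[tr]][is_case]
    q <- stats::quantile(p, probs = c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(trait = tr, median = q[2], q1 = q[1], q3 = q[3],
               n_cases = sum(is_case), n_controls = sum(is_ctrl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("case_control_summary", "data.frame")
  out
}

#' Inter-predictor correlation matrices
#'
#' Correlations between trait scores across samples in the table, mirrored
#' optionally by the same matrix computed on a reference panel's score
#' table, and optionally split by case/control status side by side. A
#' zero-variance trait yields `NA` (undefined) entries in its row and
#' column rather than a silent zero.
#'
#' @param t A [score_table()] with at least 3 samples.
#' @param traits Traits to correlate (at least 2); default all.
#' @param panel Optional [reference_panel()] with `reference_scores`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param phenotypes,phenotype Optional phenotype table and name; when
#'   given, per-status matrices for cases and controls are also returned.
#' @return A list with elements `input` (correlation matrix), optionally
#'   `reference`, and optionally `cases`/`controls`.
#' @export
score_correlations <- function(t, traits = score_traits(t), panel = NULL,
                               method = c("pearson", "spearman"),
                               phenotypes = NULL, phenotype = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(t, "score_table"))
  if (length(traits) < 2L)
    stop("need at least 2 traits to correlate", call. = FALSE)
  if (nrow(t) < 3L)
    stop("need at least 3 samples after filtering to compute correlations",
         call. = FALSE)
  cor_block <- function(df) {
    x <- as.matrix(df[, traits, drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    out <- suppressWarnings(stats::cor(x, method = method,
                                       use = "pairwise.complete.obs"))
    out[sds == 0, ] <- NA_real_
    out[, sds == 0] <- NA_real_
    diag(out)[sds > 0] <- 1
    out
  }
  res <- list(input = cor_block(t))
  if (!is.null(panel) && !is.null(panel$reference_scores)) {
    ref <- panel$reference_scores
    have <- intersect(traits, names(ref))
    if (length(have) >= 2L) {
      x <- as.matrix(ref[, have, drop = FALSE])
      res$reference <- suppressWarnings(
        stats::cor(x, method = method, use = "pairwise.complete.obs"))
    }
  }
  if (!is.null(phenotypes) && !is.null(phenotype)) {
    status <- phenotypes[[phenotype]][match(t$ID, phenotypes$ID)]
    for (grp in c("cases", "controls")) {
      wanted <- if (grp == "cases") 1L else 0L
      sub <- t[!is.na(status) & status == wanted, , drop = FALSE]
      if (nrow(sub) >= 3L) res[[grp]] <- cor_block(sub)
    }
  }
  res
}

#' Predicted-versus-measured correlations in the reference cohort
#'
#' For each requested trait, the correlation between the reference
#' cohort's predicted scores and its measured phenotype values, restricted
#' to reference individuals passing the age/sex filter. Traits without
#' paired measurements are reported as unavailable (`NA` with a note),
#' never as an error.
#'
#' @param panel A [reference_panel()] carrying `reference_scores` and
#'   `reference_phenotypes`.
#' @param traits Traits to report.
#' @param filter A [cohort_filter()] (age range and sex; status does not
#'   apply to the reference cohort).
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame with columns `trait`, `r`, `n`, `note`.
#' @export
reference_trait_correlations <- function(panel, traits,
                                         filter = cohort_filter(),
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "reference_panel"))
  unavailable <- function(tr, note, n = 0L)
    data.frame(trait = tr, r = NA_real_, n = n, note = note,
               stringsAsFactors = FALSE)
  if (is.null(panel$reference_scores) || is.null(panel$reference_phenotypes))
    return(do.call(rbind, lapply(traits, unavailable,
                                 note = "panel carries no paired reference data")))
  sc <- panel$reference_scores
  ph <- panel$reference_phenotypes
  keep <- rep(TRUE, nrow(sc))
  if ("Age" %in% names(sc))
    keep <- keep & !is.na(sc$Age) & sc$Age >= filter$age_range[1] &
      sc$Age <= filter$age_range[2]
  if (filter$sex != "both" && "Sex" %in% names(sc))
    keep <- keep & !is.na(sc$Sex) & sc$Sex == filter$sex
  rows <- lapply(traits, function(tr) {
    if (!tr %in% names(sc) || !tr %in% names(ph))
      return(unavailable(tr, "no paired reference data for this trait"))
    x <- sc[[tr]][keep]; y <- ph[[tr]][keep]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L)
      return(unavailable(tr, "fewer than 3 reference pairs after filtering",
                         n = sum(ok)))
    data.frame(trait = tr, r = stats::cor(x[ok], y[ok], method = method),
               n = sum(ok), note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
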