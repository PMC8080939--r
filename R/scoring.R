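#' Predictor model
#'
#' A methylation-based predictor (episcore) is a linear model: a named set
#' of per-CpG weights plus an intercept. A sample's predicted value is the
#' intercept plus the sum of weight times beta value over the model's CpG
#' sites, optionally followed by an output transform that undoes a log
#' transform applied to the phenotype at training time.
#'
#' @param trait_name Trait label, e.g. `"BMI"` or `"Epigenetic_Age"`.
#' @param weights Named numeric vector: CpG id to weight.
#' @param intercept Intercept, default 0.
#' @param units `"arbitrary"` (most lifestyle episcores, given meaning via
#'   percentile ranks) or `"years"` (an age clock, reported directly).
#' @param output_transform `"identity"`, `"exp"` (inverse of a natural-log
#'   phenotype transform) or `"expm1"` (inverse of log(x + 1)).
#' @return A `predictor_model` object.
#' @export
predictor_model <- function(trait_name, weights, intercept = 0,
                            units = c("arbitrary", "years"),
                            output_transform = c("identity", "exp", "expm1")) {
  units <- match.arg(units)
  output_transform <- match.arg(output_transform)
  weights <- unlist(weights)
  if (length(weights) == 0L)
    stop("predictor '", trait_name, "' has no weights", call. = FALSE)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by CpG id", call. = FALSE)
  if (anyDuplicated(names(weights)))
    stop("duplicate CpG ids in weights for '", trait_name, "'",
         call. = FALSE)
  structure(
    list(trait_name = trait_name, weights = weights,
         intercept = as.numeric(intercept), units = units,
         output_transform = output_transform),
    class = "predictor_model"
  )
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("predictor_model '%s': %d CpG weights, intercept %.4g, units=%s%s\n",
              x$trait_name, length(x$weights), x$intercept, x$units,
              if (x$output_transform != "identity")
                paste0(", transform=", x$output_transform) else ""))
  invisible(x)
}

apply_output_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         exp = exp(x),
         expm1 = expm1(x))
}

#' Score samples against one predictor
#'
#' Computes, for each sample i, `S_i = b0 + sum_j w_j * beta_ij` over the
#' model's CpG sites, then applies the model's output transform. The matrix
#' must be on the beta scale and, after the reference-fill step, contain
#' every CpG the model weights — a missing probe or a residual missing
#' value here is a contract violation, not something to paper over.
#'
#' @param m A `methyl_matrix` on the beta scale.
#' @param model A [predictor_model()].
#' @return Named numeric vector of scores in `sample_ids(m)` order.
#' @export
compute_score <- function(m, model) {
  stopifnot(inherits(m, "methyl_matrix"), inherits(model, "predictor_model"))
  if (m$scale != "beta")
    stop("scoring requires beta values; convert with m_to_beta() first",
         call. = FALSE)
  needed <- names(model$weights)
  absent <- setdiff(needed, cpg_ids(m))
  if (length(absent))
    stop("matrix lacks CpG(s) required by predictor '", model$trait_name,
         "': ", paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ..." else "",
         " (run fill_missing_cpgs() first)", call. = FALSE)
  block <- m$values[, needed, drop = FALSE]
  if (anyNA(block))
    stop("missing beta values remain at CpGs used by predictor '",
         model$trait_name, "' (run impute_missing_values() first)",
         call. = FALSE)
  raw <- drop(block %*% model$weights) + model$intercept
  out <- apply_output_transform(raw, model$output_transform)
  stats::setNames(as.numeric(out), sample_ids(m))
}

# Canonical trait-column order: the age clock first, then the lifestyle and
# biochemical traits in their conventional listing order, then extras
# alphabetically.
.canonical_traits <- c("Epigenetic_Age", "Age", "Alcohol", "Body_Fat",
                       "BMI", "HDL", "Smoking", "WHR")

order_traits <- function(models) {
  names_ <- vapply(models, function(m) m$trait_name, character(1))
  units <- vapply(models, function(m) m$units, character(1))
  canon <- match(names_, .canonical_traits)
  canon[is.na(canon)] <- length(.canonical_traits) + 1L
  order(units != "years", canon, names_)
}

#' Score table
#'
#' One row per sample: `ID`, optional `Sex` and `Age` annotation columns
#' (chronological age in years), then one predicted-value column per trait.
#' Attributes record which columns are traits and which traits are
#' expressed in years; the per-sample age source (`"true"` when a
#' chronological age is present, `"epigenetic"` otherwise) drives the age
#' fallback rule used when subsetting by age range.
#'
#' @param df Data frame with an `ID` column.
#' @param traits Character vector naming the trait columns of `df`.
#' @param years_traits Subset of `traits` reported in years.
#' @return A `score_table` data frame.
#' @export
score_table <- function(df, traits, years_traits = character()) {
  stopifnot(is.data.frame(df), "ID" %in% names(df))
  missing_traits <- setdiff(traits, names(df))
  if (length(missing_traits))
    stop("trait column(s) absent from table: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  df$ID <- as.character(df$ID)
  if (anyDuplicated(df$ID))
    stop("duplicate sample ids in score table", call. = FALSE)
  age_source <- if ("Age" %in% names(df))
    ifelse(is.na(df$Age), "epigenetic", "true")
  else rep("epigenetic", nrow(df))
  structure(df,
            traits = traits,
            years_traits = intersect(years_traits, traits),
            age_source = age_source,
            class = c("score_table", "data.frame"))
}

#' @rdname score_table
#' @param t A `score_table`.
#' @export
score_traits <- function(t) attr(t, "traits")

#' @rdname score_table
#' @export
years_traits <- function(t) attr(t, "years_traits")

# Effective age per sample: chronological when available, the epigenetic
# (years-unit) trait prediction otherwise.
effective_age <- function(t) {
  age <- if ("Age" %in% names(t)) as.numeric(t$Age) else rep(NA_real_, nrow(t))
  yrs <- years_traits(t)
  if (length(yrs)) {
    epi <- as.numeric(t[[yrs[1L]]])
    age[is.na(age)] <- epi[is.na(age)]
  }
  age
}

#' Compute a score table for a set of predictors
#'
#' Scores the matrix against every model, orders trait columns
#' canonically (the years-unit clock first), and joins sex/age annotations
#' when provided. Annotation rows whose `ID` does not appear in the matrix
#' are dropped with a QC note; matrix samples without an annotation row get
#' `NA` sex and age, and their age-range subsetting falls back to the
#' epigenetic age prediction.
#'
#' @param m A preprocessed `methyl_matrix` (beta scale, complete for every
#'   model's CpGs).
#' @param models List of [predictor_model()] objects with unique trait
#'   names.
#' @param annotations Optional [read_sample_annotations()] data frame.
#' @param qc Optional [qc_report()].
#' @return A [score_table()].
#' @export
compute_score_table <- function(m, models, annotations = NULL, qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"), length(models) >= 1L)
  if (inherits(models, "predictor_model")) models <- list(models)
  trait_names <- vapply(models, function(x) x$trait_name, character(1))
  if (anyDuplicated(trait_names))
    stop("duplicate trait names across models: ",
         paste(unique(trait_names[duplicated(trait_names)]), collapse = ", "),
         call. = FALSE)
  models <- models[order_traits(models)]
  trait_names <- vapply(models, function(x) x$trait_name, character(1))
  df <- data.frame(ID = sample_ids(m), stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    idx <- match(df$ID, annotations$ID)
    n_unmatched <- sum(!annotations$ID %in% df$ID)
    if (n_unmatched > 0)
      qc_add(qc, "annotations",
             sprintf("%d annotation row(s) had ids not in the matrix and were dropped",
                     n_unmatched),
             count = n_unmatched)
    df$Sex <- annotations$Sex[idx]
    df$Age <- annotations$Age[idx]
  }
  for (mod in models) df[[mod$trait_name]] <- unname(compute_score(m, mod))
  yrs <- trait_names[vapply(models, function(x) x$units, character(1)) == "years"]
  qc_add(qc, "score",
         sprintf("scores computed for %d trait(s) across %d sample(s)",
                 length(models), nrow(df)),
         count = nrow(df))
  score_table(df, traits = trait_names, years_traits = yrs)
}

#' Read and write score tables
#'
#' The on-disk form is a plain CSV: `ID`, optional `Sex` and `Age`, then
#' one column per trait, with missing values written as the literal `NA`.
#' Reading back what was written reproduces the table exactly, including
#' column order; unknown extra columns are preserved and treated as
#' additional (arbitrary-unit) traits.
#'
#' @param t A [score_table()].
#' @param path File path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns a [score_table()].
#' @export
write_score_table <- function(t, path) {
  stopifnot(inherits(t, "score_table"))
  data.table::fwrite(as.data.frame(t), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @param years_traits Traits expressed in years; defaults to the column
#'   named `Epigenetic_Age` when present.
#' @export
read_score_table <- function(path, years_traits = "Epigenetic_Age") {
  df <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  if ("Sex" %in% names(df)) df$Sex <- as.character(df$Sex)
  if (!"ID" %in% names(df))
    stop("score table must have an 'ID' column; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  traits <- setdiff(names(df), c("ID", "Sex", "Age"))
  if (length(traits) == 0L)
    stop("score table has no trait columns (expected ID[,Sex,Age] plus ",
         "one numeric column per trait)", call. = FALSE)
  non_num <- traits[!vapply(df[traits], is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric trait column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  df$ID <- as.character(df$ID)
  score_table(df, traits = traits,
              years_traits = intersect(years_traits, traits))
}

#' Read predictor models from a weight file
#'
#' Weight files are CSVs with columns `CpG`, `Weight` and optionally
#' `Trait` (absent means a single predictor named by `default_trait`).
#' Rows whose `CpG` field is `(Intercept)` carry the model intercept.
#' Units and output transforms are declared per trait via the `units` and
#' `transforms` arguments (or a manifest produced by
#' [write_predictor_models()]).
#'
#' @param path Weight file path.
#' @param default_trait Trait name used when the file has no `Trait`
#'   column.
#' @param units Named character vector trait -> `"years"`/`"arbitrary"`;
#'   unlisted traits default to `"arbitrary"`.
#' @param transforms Named character vector trait -> output transform;
#'   unlisted traits default to `"identity"`.
#' @return A named list of [predictor_model()] objects.
#' @export
read_predictor_models <- function(path, default_trait = "Trait",
                                  units = c(Epigenetic_Age = "years"),
                                  transforms = character()) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("CpG", "Weight") %in% names(dt)))
    stop("weight file must have columns CpG,Weight[,Trait]", call. = FALSE)
  if (!"Trait" %in% names(dt)) dt$Trait <- default_trait
  dt$CpG <- as.character(dt$CpG)
  dt$Trait <- as.character(dt$Trait)
  models <- lapply(split(dt, dt$Trait), function(g) {
    is_int <- g$CpG %in% c("(Intercept)", "Intercept")
    trait <- g$Trait[1L]
    predictor_model(
      trait_name = trait,
      weights = stats::setNames(as.numeric(g$Weight[!is_int]),
                                g$CpG[!is_int]),
      intercept = if (any(is_int)) sum(as.numeric(g$Weight[is_int])) else 0,
      units = if (!is.na(u <- units[trait])) u else "arbitrary",
      output_transform = if (!is.na(tr <- transforms[trait])) tr
                         else "identity"
    )
  })
  models[order(match(names(models), unique(dt$Trait)))]
}

#' Write predictor models to a weight file
#'
#' Emits the `CpG,Weight,Trait` layout [read_predictor_models()] reads,
#' with one `(Intercept)` row per model whose intercept is non-zero.
#' Weights are printed with 17 significant digits so that identical models
#' always serialize to byte-identical files.
#'
#' @param models A [predictor_model()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictor_models <- function(models, path) {
  if (inherits(models, "predictor_model")) models <- list(models)
  lines <- c("CpG,Weight,Trait")
  for (mod in models) {
    if (mod$intercept != 0)
      lines <- c(lines, sprintf("(Intercept),%s,%s",
                                format_weight(mod$intercept), mod$trait_name))
    lines <- c(lines, sprintf("%s,%s,%s", names(mod$weights),
                              vapply(unname(mod$weights), format_weight,
                                     character(1)),
                              mod$trait_name))
  }
  writeLines(lines, path)
  invisible(path)
}

format_weight <- function(x) sprintf("%.17g", x)

#' All CpG ids required by a set of models
#'
#' @param models A [predictor_model()] or list of them.
#' @return Character vector of unique CpG ids.
#' @export
model_cpgs <- function(models) {
  if (inherits(models, "predictor_model")) models <- list(models)
  unique(unlist(lapply(models, function(m) names(m$weights))))
}
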