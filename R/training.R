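#' Phenotype specification
#'
#' How a raw phenotype is prepared before predictor training: exclusion
#' bounds applied first (e.g. body-mass-index values below 17 or above 50
#' kg/m^2 removed as extreme), then a skew-reducing transform (`"log"` for
#' natural log, `"log1p"` for log(x + 1) — the convention for zero-heavy
#' exposures such as weekly alcohol units or smoking pack years).
#'
#' @param name Phenotype name.
#' @param transform `"none"`, `"log"` or `"log1p"`.
#' @param lower,upper Inclusive retention bounds; values outside are
#'   excluded before transformation.
#' @param unit Free-text unit label.
#' @return A `phenotype_spec` object.
#' @export
phenotype_spec <- function(name, transform = c("none", "log", "log1p"),
                           lower = -Inf, upper = Inf, unit = "") {
  transform <- match.arg(transform)
  stopifnot(is.finite(lower) || lower == -Inf,
            is.finite(upper) || upper == Inf, lower <= upper)
  structure(list(name = name, transform = transform, lower = lower,
                 upper = upper, unit = unit),
            class = "phenotype_spec")
}

#' Prepare a phenotype for training
#'
#' Applies the spec's exclusion bounds, then its transform, to a numeric
#' phenotype vector. Missing values and excluded values are dropped from
#' the retained mask; a transform that is undefined for a retained value
#' (log of a non-positive value) is a hard error naming the samples.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param spec A [phenotype_spec()].
#' @return A list: `values` (full-length, transformed, `NA` where not
#'   retained), `retained` (logical mask), `log` (character description of
#'   exclusions).
#' @export
transform_phenotype <- function(values, spec) {
  stopifnot(inherits(spec, "phenotype_spec"))
  values <- as.numeric(values)
  retained <- !is.na(values) & values >= spec$lower & values <= spec$upper
  n_excluded <- sum(!is.na(values) & !retained)
  out <- rep(NA_real_, length(values))
  v <- values[retained]
  if (spec$transform == "log") {
    bad <- which(retained)[v <= 0]
    if (length(bad))
      stop("log transform undefined for non-positive ", spec$name,
           " value(s) at sample index ", paste(bad, collapse = ", "),
           call. = FALSE)
    v <- log(v)
  } else if (spec$transform == "log1p") {
    bad <- which(retained)[v <= -1]
    if (length(bad))
      stop("log1p transform undefined for ", spec$name,
           " value(s) <= -1 at sample index ", paste(bad, collapse = ", "),
           call. = FALSE)
    v <- log1p(v)
  }
  out[retained] <- v
  log_msg <- sprintf(
    "%s: %d missing, %d excluded outside [%s, %s], %d retained (transform=%s)",
    spec$name, sum(is.na(values)), n_excluded, format(spec$lower),
    format(spec$upper), sum(retained), spec$transform)
  list(values = out, retained = retained, log = log_msg)
}

#' Residualize a phenotype on covariates
#'
#' Regresses the (transformed) phenotype on an intercept, age, sex and the
#' ancestry components by ordinary least squares and returns the
#' residuals — the pre-correction step that removes the influence of age,
#' sex and ancestry before penalized-regression training.
#'
#' @param values Numeric phenotype vector, no missing values.
#' @param covariates Data frame or matrix, row-aligned with `values`,
#'   containing `age`, `sex` (coded Female = 0, Male = 1) and the ancestry
#'   components (by default ten, named `PC1`...`PC10` or any numeric
#'   columns beyond age/sex).
#' @return Numeric residual vector with mean zero.
#' @export
precorrect_phenotype <- function(values, covariates) {
  values <- as.numeric(values)
  x <- as.matrix(as.data.frame(covariates))
  if (anyNA(values) || anyNA(x))
    stop("pre-correction requires complete phenotype and covariate data",
         call. = FALSE)
  if (nrow(x) != length(values))
    stop("covariates are not row-aligned with the phenotype", call. = FALSE)
  if (length(values) <= ncol(x) + 1L)
    stop("too few samples (", length(values), ") for ", ncol(x),
         " covariates plus intercept", call. = FALSE)
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qrd, values))
}

#' Restrict probes to an array-intersection list
#'
#' Training is confined to probes present on both array generations (450k
#' and EPIC) so that resulting predictors apply to either platform. The
#' intersection list is an external input; the package ships only a
#' synthetic stand-in.
#'
#' @param m A `methyl_matrix`.
#' @param intersection_list Character vector of CpG ids.
#' @param qc Optional [qc_report()].
#' @return A `methyl_matrix` restricted to the list; empty result is a
#'   hard error.
#' @export
filter_probes_to_array_intersection <- function(m, intersection_list,
                                                qc = NULL) {
  stopifnot(inherits(m, "methyl_matrix"))
  if (length(intersection_list) == 0L)
    stop("empty array-intersection probe list", call. = FALSE)
  keep <- cpg_ids(m) %in% intersection_list
  if (!any(keep))
    stop("no probes remain after array-intersection filtering",
         call. = FALSE)
  qc_add(qc, "probe_filter",
         sprintf("probes filtered to array intersection: %d of %d retained",
                 sum(keep), ncol(m$values)),
         count = sum(keep))
  methyl_matrix(m$values[, keep, drop = FALSE], scale = m$scale,
                orientation_log = m$orientation_log)
}

#' Training configuration
#'
#' Penalized-regression settings: the elastic-net mixing parameter alpha
#' (1 = LASSO), the number of cross-validation folds, the lambda selection
#' rule (the value minimizing mean cross-validation error) and the seed
#' that fixes fold assignment.
#'
#' @param alpha Mixing parameter in \[0, 1\]; default 1 (LASSO).
#' @param n_folds Number of CV folds; default 10.
#' @param lambda_rule Only `"min_cv_error"` is implemented.
#' @param seed Integer seed for fold assignment.
#' @return A `training_config` object.
#' @export
training_config <- function(alpha = 1, n_folds = 10,
                            lambda_rule = "min_cv_error", seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2)
  lambda_rule <- match.arg(lambda_rule, "min_cv_error")
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_rule = lambda_rule, seed = as.integer(seed)),
            class = "training_config")
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Train a penalized-regression predictor
#'
#' Fits an elastic-net path with K-fold cross-validation over lambda,
#' selects the lambda with minimum mean cross-validation error, and
#' returns the full-data model refit at that lambda as a sparse weight
#' map plus intercept. Predictors are standardized internally for the
#' penalty; the returned weights are on the raw beta scale so that the
#' scoring module's plain dot product applies them directly. Fold
#' assignment is a deterministic shuffle from the config seed.
#'
#' @param m A `methyl_matrix`, beta scale, no missing values.
#' @param residualized_phenotype Numeric vector aligned with
#'   `sample_ids(m)` (typically the output of [precorrect_phenotype()]).
#' @param cfg A [training_config()].
#' @param trait_name Name for the resulting model.
#' @return A [predictor_model()] with the non-zero weights, plus
#'   attributes `lambda_min` and `cv_error` (mean CV error at the chosen
#'   lambda).
#' @export
train_predictor <- function(m, residualized_phenotype,
                            cfg = training_config(),
                            trait_name = "Trait") {
  stopifnot(inherits(m, "methyl_matrix"), inherits(cfg, "training_config"))
  y <- as.numeric(residualized_phenotype)
  if (m$scale != "beta")
    stop("training requires beta values", call. = FALSE)
  if (anyNA(m$values) || anyNA(y))
    stop("training requires complete data; impute/fill first", call. = FALSE)
  n <- nrow(m$values)
  if (length(y) != n)
    stop("phenotype is not aligned with the matrix samples", call. = FALSE)
  if (cfg$n_folds > n)
    stop("more folds (", cfg$n_folds, ") than samples (", n, ")",
         call. = FALSE)
  if (stats::sd(y) == 0)
    stop("zero-variance phenotype", call. = FALSE)
  foldid <- with_seed(cfg$seed,
                      sample(rep(seq_len(cfg$n_folds), length.out = n)))
  cvfit <- glmnet::cv.glmnet(m$values, y, alpha = cfg$alpha,
                             foldid = foldid, family = "gaussian",
                             standardize = TRUE, nlambda = 100)
  lambda_min <- cvfit$lambda.min
  co <- stats::coef(cvfit, s = "lambda.min")
  co_num <- as.numeric(co)
  co_names <- rownames(co)
  intercept <- co_num[co_names == "(Intercept)"]
  w <- co_num[co_names != "(Intercept)"]
  names(w) <- co_names[co_names != "(Intercept)"]
  w <- w[w != 0]
  if (length(w) == 0L) {
    # Null model: keep the single largest-magnitude coefficient on the
    # path so that downstream scoring still has a weight to apply, but
    # flag the situation.
    warning("cross-validation selected the empty model for '", trait_name,
            "'; returning intercept-only predictor with a zero weight on ",
            "the first probe", call. = FALSE)
    w <- stats::setNames(0, cpg_ids(m)[1L])
  }
  model <- predictor_model(trait_name, weights = w, intercept = intercept)
  attr(model, "lambda_min") <- lambda_min
  attr(model, "cv_error") <- cvfit$cvm[cvfit$lambda == lambda_min]
  attr(model, "n_selected") <- sum(model$weights != 0)
  model
}

#' Evaluate a predictor on held-out data
#'
#' Correlates predicted scores with observed phenotype values in a test
#' sample. Reports the correlation `r`, squared correlation `R2` (the
#' conventional variance-explained figure for episcores) and the root
#' mean squared error in phenotype units. Constant predictions leave `r`
#' undefined; by convention `R2` is then 0.
#'
#' @param model A [predictor_model()].
#' @param test_m A `methyl_matrix` of held-out samples (beta scale,
#'   complete for the model's CpGs).
#' @param test_phenotype Numeric vector aligned with the test samples.
#' @return A list with elements `r`, `R2`, `RMSE`, `n`.
#' @export
evaluate_predictor <- function(model, test_m, test_phenotype) {
  pred <- compute_score(test_m, model)
  obs <- as.numeric(test_phenotype)
  stopifnot(length(obs) == length(pred))
  rmse <- sqrt(mean((pred - obs)^2))
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    return(list(r = NA_real_, R2 = 0, RMSE = rmse, n = length(obs)))
  }
  r <- stats::cor(pred, obs)
  list(r = r, R2 = r^2, RMSE = rmse, n = length(obs))
}
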