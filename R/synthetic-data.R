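#' Cohort simulation settings
#'
#' Describes a synthetic blood-methylation cohort with known ground truth:
#' per-CpG mean beta values drawn from a mixture of hypo-, hemi- and
#' hyper-methylated modes (mimicking the bimodality of real array data),
#' per-sample beta values dispersed around those means, a sparse causal
#' weight set generating a quantitative phenotype, a binary status derived
#' by thresholding the noise-free signal, sample annotations, and a larger
#' reference cohort from which probe means and comparison panels are
#' summarized.
#'
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @param n_samples Number of uploaded samples (default 50).
#' @param n_cpgs Number of simulated CpG probes (default 200).
#' @param n_causal Number of causal probes for the simulated trait
#'   (default 10).
#' @param causal_effects Optional named numeric vector of causal weights;
#'   overrides `n_causal`.
#' @param noise_sd Phenotype noise standard deviation. The default `NULL`
#'   sets it to the standard deviation of the realized noise-free signal,
#'   i.e. a signal variance fraction of one half.
#' @param missing_cell_rate Fraction of matrix cells masked missing
#'   (default 0.02, a light scatter as left by probe-quality filtering).
#' @param n_missing_cpgs Number of causal-set probes withheld entirely from
#'   the "uploaded" matrix (default 2), exercising reference fill.
#' @param age_range Uniform range for chronological ages (default adult
#'   blood-donor range 30-75 years).
#' @param age_missing_rate Fraction of samples with missing age (default
#'   0.2), exercising the epigenetic-age fallback.
#' @param age_effect,sex_effect Optional additive covariate effects
#'   injected into the phenotype (per year, and Male minus Female), so that
#'   pre-correction has real work to do; both default to 0.
#' @param case_fraction Fraction of samples labelled cases by thresholding
#'   the latent signal (default 0.5).
#' @param n_reference Size of the reference cohort draw (default 500; a
#'   scaled-down stand-in for a large population reference panel).
#' @return A `cohort_simulation` object.
#' @export
cohort_simulation <- function(seed = 1, n_samples = 50, n_cpgs = 200,
                              n_causal = 10, causal_effects = NULL,
                              noise_sd = NULL, missing_cell_rate = 0.02,
                              n_missing_cpgs = 2,
                              age_range = c(30, 75),
                              age_missing_rate = 0.2,
                              age_effect = 0, sex_effect = 0,
                              case_fraction = 0.5, n_reference = 500) {
  stopifnot(n_samples >= 1, n_cpgs >= 1,
            missing_cell_rate >= 0, missing_cell_rate <= 1,
            age_missing_rate >= 0, age_missing_rate <= 1,
            case_fraction > 0, case_fraction < 1)
  if (is.null(causal_effects) && n_causal > n_cpgs)
    stop("more causal CpGs than simulated CpGs", call. = FALSE)
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 n_cpgs = n_cpgs, n_causal = n_causal,
                 causal_effects = causal_effects, noise_sd = noise_sd,
                 missing_cell_rate = missing_cell_rate,
                 n_missing_cpgs = n_missing_cpgs, age_range = age_range,
                 age_missing_rate = age_missing_rate,
                 age_effect = age_effect, sex_effect = sex_effect,
                 case_fraction = case_fraction, n_reference = n_reference),
            class = "cohort_simulation")
}

# Per-CpG mean betas: mixture of hypo- (mean ~0.1), hemi- (~0.5) and
# hyper-methylated (~0.9) modes, the classic bimodal-with-shoulder shape
# of array data.
draw_cpg_means <- function(n) {
  mode <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  mu <- numeric(n)
  mu[mode == 1L] <- stats::rbeta(sum(mode == 1L), 2, 18)
  mu[mode == 2L] <- stats::rbeta(sum(mode == 2L), 10, 10)
  mu[mode == 3L] <- stats::rbeta(sum(mode == 3L), 18, 2)
  pmin(pmax(mu, 0.02), 0.98)
}

draw_beta_matrix <- function(n_samples, mu, concentration = 60,
                             sample_prefix = "S") {
  n_cpgs <- length(mu)
  values <- matrix(stats::rbeta(n_samples * n_cpgs,
                                rep(mu, each = n_samples) * concentration,
                                rep(1 - mu, each = n_samples) * concentration),
                   nrow = n_samples,
                   dimnames = list(paste0(sample_prefix, seq_len(n_samples)),
                                   names(mu)))
  # keep strictly inside (0,1) so M values stay finite
  pmin(pmax(values, 1e-6), 1 - 1e-6)
}

# Deterministic internals shared by the public simulators: everything is
# re-derived from sim$seed so the two entry points agree exactly.
simulate_internal <- function(sim) {
  with_seed(sim$seed, {
    cpgs <- sprintf("cg%08d", seq_len(sim$n_cpgs))
    mu <- stats::setNames(draw_cpg_means(sim$n_cpgs), cpgs)
    beta <- draw_beta_matrix(sim$n_samples, mu)

    if (is.null(sim$causal_effects)) {
      # causal probes are drawn among variably methylated CpGs
      # (intermediate mean beta), mirroring the probes real episcores
      # select; hypo-/hyper-methylated probes have little inter-individual
      # variance to carry signal
      variable <- cpgs[mu >= 0.2 & mu <= 0.8]
      pool <- if (length(variable) >= sim$n_causal) variable else cpgs
      causal_ids <- sample(pool, sim$n_causal)
      effects <- stats::setNames(
        stats::runif(sim$n_causal, 1, 2) *
          sample(c(-1, 1), sim$n_causal, replace = TRUE),
        causal_ids)
    } else {
      effects <- sim$causal_effects
      if (!all(names(effects) %in% cpgs))
        stop("causal_effects name CpGs outside the simulated set",
             call. = FALSE)
    }

    signal <- drop(beta[, names(effects), drop = FALSE] %*% effects)
    noise_sd <- if (is.null(sim$noise_sd)) stats::sd(signal) else sim$noise_sd

    age <- stats::runif(sim$n_samples, sim$age_range[1], sim$age_range[2])
    sex <- sample(c("Female", "Male"), sim$n_samples, replace = TRUE)
    age_obs <- age
    if (sim$age_missing_rate > 0)
      age_obs[stats::runif(sim$n_samples) < sim$age_missing_rate] <- NA_real_

    phenotype <- unname(signal) + sim$age_effect * age +
      sim$sex_effect * (sex == "Male") +
      stats::rnorm(sim$n_samples, 0, noise_sd)
    status <- as.integer(signal >
                           stats::quantile(signal, 1 - sim$case_fraction))

    # mask: held-out probes first, then scattered missing cells
    held_out <- if (sim$n_missing_cpgs > 0)
      utils::head(names(effects), min(sim$n_missing_cpgs, length(effects)))
    else character()
    observed <- beta[, setdiff(cpgs, held_out), drop = FALSE]
    if (sim$missing_cell_rate > 0) {
      mask <- stats::runif(length(observed)) < sim$missing_cell_rate
      observed[mask] <- NA_real_
    }

    ref_beta <- draw_beta_matrix(sim$n_reference, mu, sample_prefix = "R")

    list(cpgs = cpgs, mu = mu, beta = beta, observed = observed,
         effects = effects, signal = signal, noise_sd = noise_sd,
         age = age, age_obs = age_obs, sex = sex,
         phenotype = phenotype, status = status, held_out = held_out,
         ref_beta = ref_beta)
  })
}

#' Simulate a methylation matrix
#'
#' Draws the cohort's beta matrix and returns both the complete
#' ground-truth matrix and the "uploaded" view: held-out probes dropped
#' and a scatter of cells masked missing, plus an M-value twin of the
#' uploaded view (exact inverse-logistic transform of the betas).
#'
#' @param sim A [cohort_simulation()].
#' @return A list of `methyl_matrix` objects: `complete` (all probes, no
#'   missing), `uploaded` (beta scale, probes withheld and cells masked)
#'   and `uploaded_m` (the same view on the M-value scale).
#' @export
simulate_methylation <- function(sim) {
  stopifnot(inherits(sim, "cohort_simulation"))
  g <- simulate_internal(sim)
  uploaded <- methyl_matrix(g$observed, scale = "beta")
  list(
    complete = methyl_matrix(g$beta, scale = "beta"),
    uploaded = uploaded,
    uploaded_m = beta_to_m(uploaded)
  )
}

#' Simulate predictors, phenotypes, annotations and a reference panel
#'
#' Returns the generating predictor model (the causal weights), the
#' quantitative phenotype (`signal + covariate effects + noise`), sample
#' annotations with the configured fraction of missing ages, a binary
#' phenotype table derived by thresholding the noise-free signal, and a
#' reference panel whose probe means are the column means of an
#' independent reference draw and whose score/phenotype tables back the
#' comparison panels.
#'
#' @param sim A [cohort_simulation()].
#' @return A list with elements `model` ([predictor_model()]), `phenotype`
#'   (numeric), `signal` (noise-free component), `annotations`,
#'   `phenotypes` (binary status table), `panel` ([reference_panel()]) and
#'   `noise_sd` (the noise level actually used).
#' @export
simulate_predictor_and_phenotypes <- function(sim) {
  stopifnot(inherits(sim, "cohort_simulation"))
  g <- simulate_internal(sim)
  if (length(g$effects) == 0L)
    stop("empty causal set", call. = FALSE)
  model <- predictor_model("Trait", weights = g$effects)
  ids <- rownames(g$beta)
  annotations <- structure(
    data.frame(ID = ids, Sex = g$sex, Age = g$age_obs,
               stringsAsFactors = FALSE),
    class = c("sample_annotations", "data.frame"))
  phenotypes <- structure(
    data.frame(ID = ids, Status = g$status, stringsAsFactors = FALSE),
    class = c("phenotype_table", "data.frame"))

  ref_signal <- drop(g$ref_beta[, names(g$effects), drop = FALSE] %*%
                       g$effects)
  ref_noise <- with_seed(sim$seed + 1L,
                         stats::rnorm(sim$n_reference, 0, g$noise_sd))
  ref_demo <- with_seed(sim$seed + 2L, list(
    age = stats::runif(sim$n_reference, sim$age_range[1], sim$age_range[2]),
    sex = sample(c("Female", "Male"), sim$n_reference, replace = TRUE)))
  panel <- reference_panel(
    cpg_means = colMeans(g$ref_beta),
    reference_scores = data.frame(Age = ref_demo$age, Sex = ref_demo$sex,
                                  Trait = ref_signal,
                                  stringsAsFactors = FALSE),
    reference_phenotypes = data.frame(Trait = ref_signal + ref_noise,
                                      stringsAsFactors = FALSE),
    provenance = sprintf("synthetic reference draw (n=%d, seed=%d)",
                         sim$n_reference, sim$seed))
  list(model = model, phenotype = g$phenotype, signal = g$signal,
       annotations = annotations, phenotypes = phenotypes, panel = panel,
       noise_sd = g$noise_sd, held_out_cpgs = g$held_out)
}

#' Write a complete fixture bundle
#'
#' Materializes every file the command-line workflows consume, shaped like
#' the example bundle distributed with the original platform: the
#' methylation upload (M values, CpGs as rows, so that orientation and
#' scale handling both have work to do), the sex/age annotation file, the
#' binary phenotype file, the probe-truncation list, the weight file and
#' the reference panel files. Regenerating with the same simulation yields
#' byte-identical files.
#'
#' @param sim A [cohort_simulation()].
#' @param directory Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(sim, directory) {
  stopifnot(inherits(sim, "cohort_simulation"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  mats <- simulate_methylation(sim)
  truth <- simulate_predictor_and_phenotypes(sim)
  paths <- c(
    matrix = file.path(directory, "dnam_matrix.csv"),
    sexage = file.path(directory, "SexAgeInfo.csv"),
    phenotypes = file.path(directory, "case_control.csv"),
    cpg_list = file.path(directory, "truncate_to_these_cpgs.csv"),
    weights = file.path(directory, "weights.csv"),
    panel_means = file.path(directory, "reference_panel.csv"),
    panel_scores = file.path(directory, "reference_scores.csv"),
    panel_phenotypes = file.path(directory, "reference_phenotypes.csv")
  )
  write_methylation_matrix(mats$uploaded_m, paths["matrix"],
                           cpgs_as_rows = TRUE)
  data.table::fwrite(as.data.frame(truth$annotations), paths["sexage"],
                     na = "NA", quote = FALSE)
  data.table::fwrite(as.data.frame(truth$phenotypes), paths["phenotypes"],
                     na = "NA", quote = FALSE)
  writeLines(c("CpG", cpg_ids(mats$complete)), paths["cpg_list"])
  write_predictor_models(truth$model, paths["weights"])
  write_reference_panel(truth$panel, paths["panel_means"],
                        scores_path = paths["panel_scores"],
                        phenotypes_path = paths["panel_phenotypes"])
  paths
}
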