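test_that("phenotype preparation applies exclusions then transforms", {
  spec_alc <- phenotype_spec("Alcohol", transform = "log1p", lower = 0)
  out <- transform_phenotype(c(0, exp(1) - 1, NA, -2), spec_alc)
  expect_equal(out$values, c(0, 1, NA, NA))       # log1p(0)=0, log1p(e-1)=1
  expect_identical(out$retained, c(TRUE, TRUE, FALSE, FALSE))

  spec_bmi <- phenotype_spec("BMI", transform = "log", lower = 17, upper = 50)
  out_bmi <- transform_phenotype(c(16.5, 25, 50, 51), spec_bmi)
  expect_identical(out_bmi$retained, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out_bmi$values, c(NA, log(25), log(50), NA))
  expect_match(out_bmi$log, "2 excluded")

  spec_log <- phenotype_spec("X", transform = "log")
  expect_error(transform_phenotype(c(1, 0, 2), spec_log), "index 2")
})

test_that("pre-correction projects out covariates exactly", {
  withr::with_seed(21, {
    n <- 200
    cov <- data.frame(age = stats::runif(n, 30, 75),
                      sex = stats::rbinom(n, 1, 0.5))
    for (k in 1:10) cov[[paste0("PC", k)]] <- stats::rnorm(n)

    # phenotype purely linear in covariates -> residuals ~ 0
    y_lin <- 2 + 0.1 * cov$age - 0.5 * cov$sex + 3 * cov$PC4
    expect_lt(max(abs(precorrect_phenotype(y_lin, cov))), 1e-10)

    # generic phenotype: residuals orthogonal to every covariate column
    y <- stats::rnorm(n) + 0.05 * cov$age
    res <- precorrect_phenotype(y, cov)
    expect_lt(abs(mean(res)), 1e-10)
    for (col in names(cov)) expect_lt(abs(stats::cor(res, cov[[col]])), 1e-8)

    # covariates orthogonal to the phenotype: residuals = centered phenotype
    q <- qr.Q(qr(cbind(1, as.matrix(cov))))
    y_orth <- stats::rnorm(n)
    y_orth <- y_orth - q %*% crossprod(q, y_orth)
    expect_equal(precorrect_phenotype(as.numeric(y_orth), cov),
                 as.numeric(y_orth) - mean(y_orth), tolerance = 1e-10)
  })

  expect_error(precorrect_phenotype(1:5, matrix(stats::rnorm(60), 5, 12)),
               "too few samples")
  bad <- data.frame(age = 1:30, sex = rep(0:1, 15))
  bad$dup <- bad$age * 2
  expect_error(precorrect_phenotype(stats::rnorm(30), bad), "dup")
})

test_that("array-intersection probe filtering restricts columns", {
  m <- random_beta_matrix(4, 10, seed = 13)
  half <- cpg_ids(m)[1:5]
  out <- filter_probes_to_array_intersection(m, half)
  expect_identical(cpg_ids(out), half)
  expect_identical(filter_probes_to_array_intersection(m, cpg_ids(m))$values,
                   m$values)
  expect_error(filter_probes_to_array_intersection(m, character()), "empty")
  expect_error(filter_probes_to_array_intersection(m, "cgX"), "no probes")
})

test_that("LASSO training recovers a planted sparse signal", {
  sim <- cohort_simulation(seed = 31, n_samples = 300, n_cpgs = 120,
                           n_causal = 5, missing_cell_rate = 0,
                           n_missing_cpgs = 0, age_missing_rate = 0)
  m <- simulate_methylation(sim)$complete
  truth <- simulate_predictor_and_phenotypes(sim)
  cfg <- training_config(seed = 99)
  expect_equal(cfg$alpha, 1)           # LASSO by default
  expect_equal(cfg$n_folds, 10L)
  model <- train_predictor(m, truth$phenotype, cfg, trait_name = "Sim")
  causal <- names(truth$model$weights)
  expect_true(all(causal %in% names(model$weights)))
  # recovered weights near the generating effects for the causal set
  expect_equal(model$weights[causal], truth$model$weights,
               tolerance = 0.35)
  expect_true(attr(model, "lambda_min") > 0)

  # held-out evaluation on a fresh draw from the same world
  sim2 <- cohort_simulation(seed = 32, n_samples = 300, n_cpgs = 120,
                            causal_effects = truth$model$weights,
                            noise_sd = truth$noise_sd,
                            missing_cell_rate = 0, n_missing_cpgs = 0)
  m2 <- simulate_methylation(sim2)$complete
  truth2 <- simulate_predictor_and_phenotypes(sim2)
  metrics <- evaluate_predictor(model, m2, truth2$phenotype)
  expect_gt(metrics$R2, 0.25)  # generating variance fraction is 0.5
})

test_that("training is deterministic and validates its inputs", {
  sim <- cohort_simulation(seed = 41, n_samples = 60, n_cpgs = 50,
                           n_causal = 3, missing_cell_rate = 0,
                           n_missing_cpgs = 0)
  m <- simulate_methylation(sim)$complete
  truth <- simulate_predictor_and_phenotypes(sim)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  cfg <- training_config(seed = 7)
  write_predictor_models(train_predictor(m, truth$phenotype, cfg), f1)
  write_predictor_models(train_predictor(m, truth$phenotype, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(train_predictor(m, truth$phenotype,
                               training_config(n_folds = 61)),
               "folds")
  expect_error(train_predictor(m, rep(1, 60), training_config()),
               "zero-variance")
  expect_error(train_predictor(m, truth$phenotype[-1], training_config()),
               "aligned")
})

test_that("pure-noise phenotypes yield near-empty models with CV error near var(y)", {
  sim <- cohort_simulation(seed = 51, n_samples = 100, n_cpgs = 200,
                           n_causal = 1, missing_cell_rate = 0,
                           n_missing_cpgs = 0)
  m <- simulate_methylation(sim)$complete
  y <- withr::with_seed(52, stats::rnorm(100))
  model <- suppressWarnings(
    train_predictor(m, y, training_config(seed = 5), "Null"))
  expect_lte(attr(model, "n_selected"), 10)  # null support stays small
  expect_equal(attr(model, "cv_error"), stats::var(y), tolerance = 0.35)
})

test_that("evaluation metrics behave at the degenerate corners", {
  m <- random_beta_matrix(5, 3, seed = 61)
  w <- stats::setNames(c(1, 0, 0), cpg_ids(m))
  model <- predictor_model("T", w)
  pred <- compute_score(m, model)
  perfect <- evaluate_predictor(model, m, unname(pred))
  expect_equal(perfect$r, 1); expect_equal(perfect$RMSE, 0)

  shifted <- evaluate_predictor(model, m, unname(pred) + 2.5)
  expect_equal(shifted$r, 1)
  expect_equal(shifted$RMSE, 2.5)

  flat <- predictor_model("T", stats::setNames(c(0, 0, 0), cpg_ids(m)),
                          intercept = 1)
  out <- evaluate_predictor(flat, m, stats::rnorm(5))
  expect_true(is.na(out$r)); expect_equal(out$R2, 0)
})
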