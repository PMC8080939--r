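test_that("mid-rank percentiles match the closed form and handle ties", {
  t4 <- make_score_table(list(BMI = c(1, 2, 3, 4)))
  p <- percentile_ranks(t4)
  expect_equal(p$BMI, c(12.5, 37.5, 62.5, 87.5))  # 100*(r-0.5)/4

  tied <- make_score_table(list(BMI = rep(2.2, 5)))
  expect_equal(percentile_ranks(tied)$BMI, rep(50, 5))

  one <- make_score_table(list(BMI = 3.3))
  expect_equal(percentile_ranks(one)$BMI, 50)

  # age clock passes through in years; chronological Age untouched
  t_age <- make_score_table(list(Epigenetic_Age = c(30.2, 41.7),
                                 BMI = c(1, 2)),
                            age = c(29, 43),
                            years_traits = "Epigenetic_Age")
  p_age <- percentile_ranks(t_age)
  expect_equal(p_age$Epigenetic_Age, c(30.2, 41.7))
  expect_equal(p_age$Age, c(29, 43))
  expect_equal(p_age$BMI, c(25, 75))

  expect_error(percentile_ranks(make_score_table(list(BMI = numeric()),
                                                 ids = character())),
               "empty")
})

test_that("percentiles are invariant under monotone transforms and average 50", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- stats::rnorm(37)  # tie-free almost surely
      t1 <- make_score_table(list(T1 = x))
      t2 <- make_score_table(list(T1 = exp(2 * x) + 5))  # strictly increasing
      p1 <- percentile_ranks(t1)$T1
      expect_equal(p1, percentile_ranks(t2)$T1)
      expect_equal(mean(p1), 50)           # exact for mid-rank, any n
      expect_true(all(p1 > 0 & p1 < 100))
    })
  }
})

test_that("subsetting uses effective age with the epigenetic fallback", {
  t <- make_score_table(
    list(Epigenetic_Age = c(65, 50, 45, 80), BMI = 1:4),
    sex = c("Female", "Male", NA, "Female"),
    age = c(45, NA, 70, NA),
    years_traits = "Epigenetic_Age")
  # S1: true 45 (epi 65) -> retained under [40,60]; S2: no true age, epi 50
  # -> retained; S3: true 70 -> out; S4: epi 80 -> out
  sub <- subset_cohort(t, cohort_filter(age_range = c(40, 60)))
  expect_identical(sub$ID, c("S1", "S2"))

  # sex filter excludes unknown sex
  sub_f <- subset_cohort(t, cohort_filter(sex = "Female"))
  expect_identical(sub_f$ID, c("S1", "S4"))

  # filter matching nobody yields a valid empty table
  none <- subset_cohort(t, cohort_filter(age_range = c(0, 1)))
  expect_identical(nrow(none), 0L)
  expect_s3_class(none, "score_table")
})

test_that("status filtering restricts to cases or controls and drops missing status", {
  t <- make_score_table(list(BMI = 1:5))
  ph <- data.frame(ID = paste0("S", 1:5), dz = c(1L, 0L, 1L, NA, 0L))
  cases <- subset_cohort(t, cohort_filter(status_phenotype = "dz",
                                          status = "cases"),
                         phenotypes = ph)
  expect_identical(cases$ID, c("S1", "S3"))
  ctrls <- subset_cohort(t, cohort_filter(status_phenotype = "dz",
                                          status = "controls"),
                         phenotypes = ph)
  expect_identical(ctrls$ID, c("S2", "S5"))
  expect_error(subset_cohort(t, cohort_filter(status_phenotype = "nope",
                                              status = "cases"),
                             phenotypes = ph),
               "available")
})

test_that("individual profiles agree with table-wide percentiles", {
  withr::with_seed(1, {
    x <- stats::rnorm(10)
  })
  t <- make_score_table(list(T1 = x))
  top <- t$ID[which.max(x)]
  expect_equal(unname(individual_profile(t, top, "T1")), 95)  # top of 10
  solo <- subset_cohort(t, cohort_filter())[which.max(x), , drop = FALSE]
  solo <- score_table(solo, traits = "T1")
  expect_equal(unname(individual_profile(solo, top, "T1")), 50)
  expect_error(individual_profile(t, "nobody", "T1"), "not found")
  expect_error(individual_profile(t, top, "T9"), "available")
})

test_that("case/control summaries follow the mid-rank + linear-quartile rules", {
  # single case at the top of 10: median = q1 = q3 = 95
  withr::with_seed(2, x <- sample(1:10))
  t <- make_score_table(list(T1 = x))
  ph <- data.frame(ID = t$ID, dz = as.integer(x == 10))
  s <- case_control_summary(t, ph, "dz")
  expect_equal(s$median, 95); expect_equal(s$q1, 95); expect_equal(s$q3, 95)
  expect_equal(s$n_cases, 1L); expect_equal(s$n_controls, 9L)

  # three cases whose percentiles are 25/50/75 exactly (n = 2k grid)
  t2 <- make_score_table(list(T1 = 1:2000))
  case_rows <- c(505, 1005, 1505)  # percentiles 25.225, 50.225, 75.225
  ph2 <- data.frame(ID = t2$ID,
                    dz = as.integer(seq_len(2000) %in% case_rows))
  s2 <- case_control_summary(t2, ph2, "dz")
  pct <- 100 * (case_rows - 0.5) / 2000
  expect_equal(s2$median, pct[2])
  expect_equal(s2$q1, mean(pct[1:2]))  # type-7 interpolation at n=3
  expect_equal(s2$q3, mean(pct[2:3]))
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)

  expect_warning(empty <- case_control_summary(
    t, data.frame(ID = t$ID, dz = 0L), "dz"), "no cases")
  expect_identical(nrow(empty), 0L)
})

test_that("correlation matrices are symmetric PSD with NA for zero variance", {
  withr::with_seed(7, {
    x <- stats::rnorm(100)
    t <- make_score_table(list(A = x, B = -x, C = stats::rnorm(100)))
  })
  res <- score_correlations(t)
  expect_equal(res$input["A", "A"], 1)
  expect_equal(res$input["A", "B"], -1)
  expect_equal(res$input, t(res$input))
  ev <- eigen(res$input, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))

  tz <- make_score_table(list(A = 1:5, Z = rep(3, 5)))
  rz <- score_correlations(tz)$input
  expect_true(all(is.na(rz["Z", ])) && all(is.na(rz[, "Z"])))
  expect_equal(rz["A", "A"], 1)

  expect_error(score_correlations(make_score_table(list(A = 1:2, B = 2:1))),
               "at least 3 samples")
  expect_error(score_correlations(t, traits = "A"), "at least 2 traits")
})

test_that("independent traits show near-zero correlation; status split works", {
  withr::with_seed(11, {
    t <- make_score_table(list(A = stats::rnorm(1000), B = stats::rnorm(1000)))
  })
  expect_lt(abs(score_correlations(t)$input["A", "B"]), 0.1)

  ph <- data.frame(ID = t$ID, dz = rep(c(0L, 1L), 500))
  res <- score_correlations(t, phenotypes = ph, phenotype = "dz")
  expect_true(all(c("cases", "controls") %in% names(res)))
  expect_equal(dim(res$cases), c(2, 2))
})

test_that("reference trait correlations respect filters and report unavailability", {
  withr::with_seed(5, {
    n <- 500
    score <- stats::rnorm(n)
    noise <- stats::rnorm(n, sd = 2)
    panel <- reference_panel(
      c(cg1 = 0.5),
      reference_scores = data.frame(Age = stats::runif(n, 30, 75),
                                    Sex = sample(c("Male", "Female"), n, TRUE),
                                    Exact = score, Noisy = score),
      reference_phenotypes = data.frame(Exact = score,
                                        Noisy = score + noise))
  })
  res <- reference_trait_correlations(panel, c("Exact", "Noisy", "Absent"))
  expect_equal(res$r[res$trait == "Exact"], 1, tolerance = 1e-12)
  # attenuation: generating r = 1/sqrt(1+4) ~ 0.447; allow simulation noise
  expect_equal(res$r[res$trait == "Noisy"], 1 / sqrt(5), tolerance = 0.12)
  expect_true(is.na(res$r[res$trait == "Absent"]))
  expect_match(res$note[res$trait == "Absent"], "no paired")

  out <- reference_trait_correlations(panel, "Exact",
                                      cohort_filter(age_range = c(0, 1)))
  expect_true(is.na(out$r))
  expect_match(out$note, "fewer than 3")

  bare <- reference_panel(c(cg1 = 0.5))
  res0 <- reference_trait_correlations(bare, "Exact")
  expect_true(is.na(res0$r))
})
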