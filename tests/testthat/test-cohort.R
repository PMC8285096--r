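test_that("cohort has the requested size and schema", {
  co <- simulateCohort(cohortSpec(n = 2223), seed = 1)
  expect_identical(nrow(co), 2223L)
  expect_true(all(c("non_paroxysmal_af", "age", "hypertension", "diabetes",
                    "vascular_disease", "heart_failure", "lvef", "e_em",
                    "la_diameter_mm", "peak_la_pressure_mmhg",
                    "la_wall_thickness_mm", "la_voltage_mv",
                    "stress_dyn_cm2", "stress_quartile",
                    "follow_up_months", "recurrence") %in% names(co)))
  expect_true(all(co$recurrence %in% 0:1))
  expect_true(all(co$follow_up_months >= 0))
})

test_that("binary prevalences match the spec within 3 binomial SE", {
  co <- simulateCohort(cohortSpec(n = 10000), seed = 2)
  p <- 0.471
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(co$hypertension) - p), 3 * se)
  p2 <- 0.287
  se2 <- sqrt(p2 * (1 - p2) / 10000)
  expect_lt(abs(mean(co$non_paroxysmal_af) - p2), 3 * se2)
})

test_that("cohort generation is bitwise reproducible under the seed", {
  spec <- cohortSpec(n = 300)
  expect_identical(simulateCohort(spec, seed = 7),
                   simulateCohort(spec, seed = 7))
})

test_that("a quarter of patients is labeled Q4 up to rounding", {
  co <- simulateCohort(cohortSpec(n = 1001), seed = 3)
  expect_lte(abs(sum(co$stress_quartile == "Q4") - 1001 / 4), 1)
})

test_that("stored stress satisfies the Law of Laplace row-wise", {
  co <- simulateCohort(cohortSpec(n = 500), seed = 4)
  expect_equal(lawStress(co$peak_la_pressure_mmhg, co$la_diameter_mm,
                         co$la_wall_thickness_mm),
               co$stress_dyn_cm2, tolerance = 1e-12)
})

test_that("without noise the quartile is a function of the covariates", {
  spec <- cohortSpec(n = 400, stressNoiseSD = 0)
  co <- simulateCohort(spec, seed = 5)
  lp <- with(co, 41 + 31.08 * non_paroxysmal_af + 2.91 * bmi +
                 15.36 * diabetes + 22.27 * vascular_disease +
                 4.95 * e_em - 22.24 * la_voltage_mv)
  expect_equal(co$stress_dyn_cm2, pmax(lp, 5) * 1e3, tolerance = 1e-12)
  expect_identical(as.character(co$stress_quartile),
                   as.character(quartilePartition(lp)$labels))
})

test_that("blanking rule censor zeroes out early-recurrence patients", {
  spec <- cohortSpec(n = 500, blankingRule = "censor")
  co <- simulateCohort(spec, seed = 6)
  early <- co$early_recurrence == 1
  expect_true(any(early))
  expect_true(all(co$recurrence[early] == 0))
  expect_true(all(co$follow_up_months[early] == 0))
})

test_that("missingness stressor hits only the invasive pressure", {
  co <- simulateCohort(cohortSpec(n = 1000, missingRate = 0.2), seed = 8)
  expect_gt(mean(is.na(co$peak_la_pressure_mmhg)), 0.1)
  expect_false(anyNA(co$la_diameter_mm))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(n = 4), "at least 8")
  expect_error(cohortSpec(prevalence = c(hypertension = 1.2)), "prevalences")
  expect_error(cohortSpec(censorWindow = 2, blanking = 3), "censoring window")
  expect_error(cohortSpec(stressCoef = c(bmi = NaN)), "finite")
  expect_error(cohortSpec(correlation = diag(3)), "matrix")
})

test_that("a covariate correlation matrix induces the correlation", {
  k <- 7
  cm <- diag(k)
  cm[1, 2] <- cm[2, 1] <- 0.8   # age with bmi
  co <- simulateCohort(cohortSpec(n = 5000, correlation = cm), seed = 9)
  expect_gt(cor(log(co$age), log(co$bmi)), 0.6)
})

test_that("cohort CSV round-trips", {
  co <- simulateCohort(cohortSpec(n = 50), seed = 10)
  path <- tempfile(fileext = ".csv")
  writeCohort(co, path)
  back <- readCohort(path)
  expect_equal(back$stress_dyn_cm2, co$stress_dyn_cm2, tolerance = 1e-9)
  expect_identical(as.character(back$stress_quartile),
                   as.character(co$stress_quartile))
  unlink(path)
})
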