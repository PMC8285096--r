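test_that("pressure conversion reproduces the CGS constant", {
  expect_identical(round(mmHgToDynCm2(1)), 1333)
  expect_identical(mmHgToDynCm2(0), 0)
  expect_identical(round(mmHgToDynCm2(20)), 26664)
  expect_equal(mmHgToDynCm2(2), 2 * mmHgToDynCm2(1))   # linearity
})

test_that("Law-of-Laplace stress matches direct substitution", {
  expect_identical(round(lawStress(1, 40, 2)), 6666)
  expect_identical(lawStress(0, 40, 2), 0)
  # at the cohort's median diameter and thickness, a 20 mmHg pressure
  # lands near the published median stress boundary of 139.8 x 10^3
  expect_lt(abs(lawStress(20, 41, 1.95) - 140.2e3), 500)
})

test_that("stress is homogeneous of degree 1 in P and D and -1 in h", {
  set.seed(3)
  P <- runif(20, 5, 30); D <- runif(20, 30, 50); h <- runif(20, 1.2, 3)
  a <- 1.7
  expect_equal(lawStress(a * P, D, h), a * lawStress(P, D, h))
  expect_equal(lawStress(P, a * D, h), a * lawStress(P, D, h))
  expect_equal(lawStress(P, D, a * h), lawStress(P, D, h) / a)
})

test_that("stress input guards fire", {
  expect_error(lawStress(10, 40, 0), "thickness")
  expect_error(lawStress(10, 0, 2), "diameter")
  expect_error(lawStress(-1, 40, 2), "pressure")
  expect_true(is.na(lawStress(NA, 40, 2)))
})

test_that("quartile partition splits exact quarters cleanly", {
  qp <- quartilePartition(1:8)
  expect_identical(as.numeric(qp$sizes), rep(2, 4))
  expect_identical(which(qp$labels == "Q4"), c(7L, 8L))
  expect_identical(qp$cutoffs, c(2L, 4L, 6L))
})

test_that("n = 2223 tie-free values split 556/556/555/556", {
  set.seed(4)
  v <- rnorm(2223)
  qp <- quartilePartition(v)
  expect_identical(as.numeric(qp$sizes), c(556, 556, 555, 556))
  # Q4 holds exactly the 556 largest values
  expect_identical(sort(v[qp$labels == "Q4"]), sort(v)[1668:2223])
})

test_that("quartile labels are invariant under monotone transforms", {
  set.seed(5)
  v <- rlnorm(101)
  expect_identical(quartilePartition(v)$labels,
                   quartilePartition(log(v))$labels)
  expect_identical(quartilePartition(v)$labels,
                   quartilePartition(rank(v))$labels)
})

test_that("ties are assigned to the lower group deterministically", {
  v <- c(5, 3, 3, 3, 3, 3, 3, 1)
  qp <- quartilePartition(v)
  expect_identical(as.numeric(qp$sizes), rep(2, 4))
  # the tied 3s fill Q1(partially)..Q3 in original order; 5 tops Q4
  expect_identical(as.character(qp$labels),
                   c("Q4", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q1"))
})

test_that("degenerate quartile inputs are rejected", {
  expect_error(quartilePartition(rep(1, 10)), "identical")
  expect_error(quartilePartition(c(1, 2, 3)), "at least 4")
})

test_that("cohortStress appends stress and quartile columns", {
  co <- simulateCohort(cohortSpec(n = 100), seed = 1)
  co$stress_dyn_cm2 <- NULL
  co$stress_quartile <- NULL
  out <- cohortStress(co)
  expect_true(all(c("stress_dyn_cm2", "stress_quartile") %in% names(out)))
  expect_length(attr(out, "cutoffs"), 3)
  expect_identical(attr(out, "excluded"), 0L)
  expect_error(cohortStress(co[setdiff(names(co), "la_diameter_mm")]),
               "la_diameter_mm")
})
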