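# direct product-limit computation used as the oracle for kmCurve
handKM <- function(time, event) {
  tev <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tev, surv = NA_real_)
  for (i in seq_along(tev)) {
    atRisk <- sum(time >= tev[i])
    d <- sum(time == tev[i] & event == 1)
    s <- s * (1 - d / atRisk)
    out$surv[i] <- s
  }
  out
}

test_that("two-patient product limit by hand", {
  km <- kmCurve(c(1, 2), c(1, 0))
  expect_equal(km$curve$surv[km$curve$time == 1], 0.5)
  expect_equal(min(km$curve$surv), 0.5)
})

test_that("no events means flat survival at 1", {
  km <- kmCurve(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km$curve$surv == 1))
})

test_that("KM curve equals the hand product-limit oracle", {
  set.seed(10)
  time <- round(rexp(200, 0.1), 1)
  event <- rbinom(200, 1, 0.7)
  km <- kmCurve(time, event)
  oracle <- handKM(time, event)
  got <- km$curve[km$curve$nEvent > 0, c("time", "surv")]
  expect_equal(got$time, oracle$time)
  expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(11)
  time <- rexp(150, 0.2)
  km <- kmCurve(time, rep(1, 150))
  emp <- vapply(km$curve$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$curve$surv, emp, tolerance = 1e-12)
})

test_that("negative times and bad flags are rejected", {
  expect_error(kmCurve(c(-1, 2), c(1, 0)), "negative")
  expect_error(kmCurve(c(1, 2), c(2, 0)), "0/1")
})

test_that("identical groups give a null log-rank test", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  lr <- logrankTest(rep(time, 2), rep(event, 2),
                    rep(c("A", "B"), each = 6))
  expect_lt(lr$statistic, 1e-10)
  expect_gt(lr$p.value, 0.999)
})

test_that("log-rank matches the hand observed/expected tabulation", {
  # A: events at 1, 2; B: events at 3, 4; no censoring
  time <- c(1, 2, 3, 4)
  event <- rep(1, 4)
  group <- c("A", "A", "B", "B")
  # hand tabulation: at t=1 O_A=1 E_A=2/4; t=2 O_A=1 E_A=1/3;
  # t=3 O_A=0 E_A=0; t=4 O_A=0 E_A=0 -> U = 2 - 5/6; V = sum of
  # hypergeometric variances = 1/4 + 2/9
  U <- 2 - (2 / 4 + 1 / 3)
  V <- (2 * 2) / (4 * 4 * 3) * 3 + (1 * 2) / (3 * 3 * 2) * 2
  lr <- logrankTest(time, event, group)
  expect_equal(lr$statistic, U^2 / V, tolerance = 1e-10)
  expect_equal(lr$table$observed, c(2, 2))
  expect_equal(lr$table$expected, c(2 / 4 + 1 / 3, 4 - 2 / 4 - 1 / 3),
               tolerance = 1e-12)
})

test_that("log-rank input guards fire", {
  expect_error(logrankTest(1:4, rep(0, 4), rep(c("A", "B"), 2)),
               "no events")
  expect_error(logrankTest(1:4, rep(1, 4), rep("A", 4)), "2 groups")
})

test_that("Cox fit recovers a known hazard ratio", {
  set.seed(12)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(log(2) * x))
  cens <- runif(n, 0, 40)
  df <- data.frame(follow_up_months = pmin(t, cens),
                   recurrence = as.integer(t <= cens), x = x)
  fit <- coxFit(df, "x")
  expect_gte(fit$table$hr, fit$table$lower95)
  expect_lte(fit$table$hr, fit$table$upper95)
  expect_true(fit$table$lower95 < 2 && fit$table$upper95 > 2)
  expect_lt(abs(fit$table$hr - 2), 0.3)
})

test_that("a null covariate yields an HR near 1", {
  set.seed(13)
  n <- 2000
  df <- data.frame(follow_up_months = rexp(n, 0.05),
                   recurrence = rbinom(n, 1, 0.8),
                   x = rnorm(n))
  fit <- coxFit(df, "x")
  expect_gt(fit$table$hr, 0.85)
  expect_lt(fit$table$hr, 1.18)
})

test_that("degenerate Cox designs fail loudly", {
  df <- data.frame(follow_up_months = rexp(50, 0.1),
                   recurrence = rbinom(50, 1, 0.5),
                   x = rep(1, 50))
  expect_error(suppressWarnings(coxFit(df, "x")), "zero-variance")
  # monotone likelihood: all events in one arm, none in the other
  df2 <- data.frame(follow_up_months = c(seq(1, 5, length.out = 25),
                                         rep(30, 25)),
                    recurrence = rep(c(1, 0), each = 25),
                    x = rep(c(1, 0), each = 25))
  expect_error(suppressWarnings(coxFit(df2, "x")), "perfect separation")
})

test_that("few events per covariate triggers a warning", {
  set.seed(14)
  df <- data.frame(follow_up_months = rexp(30, 0.1),
                   recurrence = rbinom(30, 1, 0.2),
                   x = rnorm(30))
  expect_warning(coxFit(df, "x"), "events")
})

test_that("p < 0.05 screening feeds the multivariate stage", {
  set.seed(15)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)          # strong true predictor
  x2 <- rnorm(n)                   # noise
  x3 <- rnorm(n)                   # noise
  t <- rexp(n, 0.04 * exp(0.9 * x1))
  cens <- runif(n, 0, 50)
  df <- data.frame(follow_up_months = pmin(t, cens),
                   recurrence = as.integer(t <= cens),
                   x1 = x1, x2 = x2, x3 = x3)
  sel <- selectThenMultivariate(df, c("x1", "x2", "x3"), model = "cox")
  expect_true("x1" %in% sel$selected)
  expect_identical(nrow(sel$univariate), 3L)
  expect_true(all(sel$multivariate$table$covariate %in% sel$selected))
  # a single passing candidate makes both stages numerically identical
  sel1 <- selectThenMultivariate(df, "x1", model = "cox")
  expect_equal(sel1$multivariate$table$hr,
               sel1$univariate$hr[1], tolerance = 1e-12)
})

test_that("null candidates pass the univariate screen at about 5%", {
  set.seed(16)
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    n <- 150
    df <- data.frame(follow_up_months = rexp(n, 0.08),
                     recurrence = rbinom(n, 1, 0.7),
                     x = rnorm(n))
    fit <- coxFit(df, "x")
    if (fit$table$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.01)
  expect_lt(hits / reps, 0.10)
})

test_that("linear association fits recover exact and noisy truths", {
  set.seed(17)
  n <- 400
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$stress_dyn_cm2 <- (2 + 3 * df$a - 1.5 * df$b) * 1e3
  fit <- suppressWarnings(linregFit(df, c("a", "b")))  # exact fit warns
  expect_equal(fit$table$beta, c(3, -1.5), tolerance = 1e-9)

  # generative oracle at the published non-paroxysmal effect size
  n <- 5000
  df2 <- data.frame(x = rbinom(n, 1, 0.3))
  df2$stress_dyn_cm2 <- (100 + 31.08 * df2$x + rnorm(n, sd = 70)) * 1e3
  fit2 <- linregFit(df2, "x")
  se <- summary(fit2$fit)$coefficients[2, "Std. Error"]
  expect_lt(abs(fit2$table$beta - 31.08), 3 * se)
  expect_true(fit2$table$lower95 < fit2$table$beta)
  expect_true(fit2$table$upper95 > fit2$table$beta)
})

test_that("exact collinearity is an error naming the dependent column", {
  df <- data.frame(a = rnorm(30))
  df$b <- 2 * df$a
  df$stress_dyn_cm2 <- rnorm(30)
  expect_error(linregFit(df, c("a", "b")), "collinearity.*b")
})
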