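test_that("perfect ranking gives AUC 1 and Gini 1", {
  m <- evaluateBinary(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_identical(m$auc, 1)
  expect_identical(m$gini, 1)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$specificity, 1)
})

test_that("uninformative predictions score near AUC 0.5", {
  set.seed(6)
  y <- rbinom(10000, 1, 0.3)
  p <- runif(10000)
  m <- evaluateBinary(y, p)
  expect_lt(abs(m$auc - 0.5), 0.02)
})

test_that("AUC agrees with the independent pROC computation", {
  set.seed(7)
  y <- rbinom(400, 1, 0.4)
  p <- plogis(rnorm(400) + y)
  m <- evaluateBinary(y, p)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("Gini is exactly 2 AUC - 1 before any rounding", {
  set.seed(8)
  for (i in 1:10) {
    y <- rbinom(200, 1, 0.25)
    if (length(unique(y)) < 2) next
    p <- runif(200)
    m <- evaluateBinary(y, p)
    expect_identical(m$gini, 2 * m$auc - 1)
  }
  # the identity maps an AUC of 0.734 to 0.468
  expect_equal(2 * 0.734 - 1, 0.468)
})

test_that("Youden threshold maximizes sensitivity + specificity", {
  y <- c(0, 0, 0, 1, 1, 1)
  p <- c(0.1, 0.2, 0.6, 0.4, 0.8, 0.9)
  m <- evaluateBinary(y, p)
  js <- vapply(sort(unique(p)), function(t) {
    mean(p[y == 1] >= t) + mean(p[y == 0] < t) - 1
  }, numeric(1))
  expect_equal(m$sensitivity + m$specificity - 1, max(js))
  mf <- evaluateBinary(y, p, thresholdRule = "fixed", threshold = 0.5)
  expect_equal(mf$sensitivity, 2 / 3)
  expect_equal(mf$specificity, 2 / 3)
})

test_that("log-loss clamps probabilities and MSE matches by hand", {
  m <- evaluateBinary(c(0, 1), c(0, 1))
  expect_true(is.finite(m$logLoss))
  expect_equal(m$mse, 0)
  m2 <- evaluateBinary(c(0, 1), c(0.5, 0.5))
  expect_equal(m2$logLoss, -log(0.5))
  expect_equal(m2$mse, 0.25)
})

test_that("single-class labels are rejected", {
  expect_error(evaluateBinary(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("logistic comparator recovers generative coefficients", {
  set.seed(9)
  n <- 5000
  x <- matrix(rnorm(n * 3), n, 3)
  colnames(x) <- c("a", "b", "c")
  beta <- c(0.8, -0.5, 0.3)
  y <- rbinom(n, 1, plogis(-0.2 + x %*% beta))
  fit <- fitLogistic(x, y)
  expect_false(fit$separation)
  se <- summary(fit$glm)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(coef(fit$glm)[-1] - beta) < 3 * se))
})

test_that("intercept-only balanced data predicts one half", {
  x <- matrix(0.5, 40, 1)   # constant feature, coefficient undefined -> NA
  colnames(x) <- "a"
  y <- rep(0:1, 20)
  fit <- suppressWarnings(fitLogistic(x, y))
  expect_true(all(abs(fit$probabilities - 0.5) < 1e-8))
})

test_that("perfect separation is flagged with a penalized fallback", {
  x <- matrix(c(1:20), 20, 1)
  colnames(x) <- "a"
  y <- as.integer(x[, 1] > 10)
  fit <- fitLogistic(x, y)
  expect_true(fit$separation)
  expect_identical(fit$engine, "glmnet-ridge")
  expect_gte(fit$metrics$auc, 0.99)
})
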