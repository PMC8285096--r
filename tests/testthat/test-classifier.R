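test_that("7:1:2 split has largest-remainder sizes and is stratified", {
  sets <- suppressWarnings(splitDataset(rep(0:1, 5), seed = 1))
  expect_identical(unname(lengths(sets)), c(7L, 1L, 2L))

  y <- rep(c(0, 1), c(150, 50))
  sets <- splitDataset(y, seed = 2)
  ix <- unname(unlist(sets))
  expect_identical(sort(ix), seq_along(y))          # disjoint + exhaustive
  for (s in sets) {
    expect_lte(abs(sum(y[s] == 1) - length(s) * 0.25), 1)
  }
  expect_identical(splitDataset(y, seed = 9), splitDataset(y, seed = 9))
  expect_false(identical(splitDataset(y, seed = 9),
                         splitDataset(y, seed = 10)))
  expect_error(splitDataset(rep(1, 20)), "both classes")
  expect_error(splitDataset(rep(0:1, 2)), "at least 10")
})

test_that("min-max scaling maps train to [0,1] and extrapolates", {
  x <- cbind(a = c(10, 20, 30), b = c(1, 2, 4))
  sc <- fitScaler(x)
  expect_equal(applyScaler(sc, x)[, "a"], c(0, 0.5, 1))
  expect_equal(unname(applyScaler(sc, cbind(a = 40, b = 2))[1, "a"]), 1.5)
  # idempotence up to affinity: rescaling scaled data with its own scaler
  xs <- applyScaler(sc, x)
  expect_true(all(xs >= 0 & xs <= 1))
  expect_warning(sc2 <- fitScaler(cbind(k = c(2, 2, 2))), "constant")
  expect_equal(unname(applyScaler(sc2, cbind(k = c(2, 5)))[, 1]), c(0, 0))
})

test_that("network architecture has the hand-counted parameter budget", {
  # conv 3x8 + 8 bias = 32; conv BN 2*8 = 16; FC 48*16+16 = 784;
  # BN 32; FC 16*4+4 = 68; BN 8; output 4+1 = 5  -> 945 total
  net <- buildQ4Net(seed = 1)
  expect_identical(netParameterCount(net), 945L)
  expect_identical(dim(net$params$Wc), c(3L, 8L))
  expect_identical(dim(net$params$W1), c(48L, 16L))
  expect_identical(dim(net$params$W2), c(16L, 4L))
})

test_that("same seed gives identical initial weights, output in (0,1)", {
  n1 <- buildQ4Net(seed = 7)
  n2 <- buildQ4Net(seed = 7)
  expect_identical(n1$params, n2$params)
  x <- matrix(rnorm(40 * 8), 40, 8)
  p <- predictQ4(n1, x)
  expect_true(all(p > 0 & p < 1))
})

test_that("cosine annealing restarts each 20-epoch cycle at 9.36e-3", {
  expect_equal(cosineAnnealingRate(1), 9.36e-3)
  expect_equal(cosineAnnealingRate(21), 9.36e-3)
  expect_equal(cosineAnnealingRate(41), 9.36e-3)
  expect_equal(cosineAnnealingRate(11), 0.5 * 9.36e-3 * (1 + cos(pi / 2)))
  lrs <- vapply(1:100, cosineAnnealingRate, numeric(1))
  expect_true(all(lrs > 0 & lrs <= 9.36e-3))
})

test_that("patience rule stops only after 10 non-improving epochs", {
  st <- earlyStopInit()
  for (loss in seq(1, 0.01, length.out = 100)) {
    st <- earlyStopUpdate(st, loss, patience = 10)
    expect_false(st$stop)
    expect_true(st$improved)
  }
  for (i in 1:9) {
    st <- earlyStopUpdate(st, 0.5, patience = 10)
    expect_false(st$stop)
  }
  st <- earlyStopUpdate(st, 0.5, patience = 10)
  expect_true(st$stop)
  expect_equal(st$best, 0.01)
})

test_that("training separates separable data to AUC >= 0.99", {
  d <- separableData(2000)
  sp <- splitDataset(d$y, seed = 1)
  sc <- fitScaler(d$x[sp$train, ])
  net <- buildQ4Net(seed = 1)
  net <- trainQ4Net(net, applyScaler(sc, d$x[sp$train, ]), d$y[sp$train],
                    applyScaler(sc, d$x[sp$validation, ]),
                    d$y[sp$validation], trainConfig(seed = 1))
  m <- evaluateBinary(d$y[sp$train],
                      predictQ4(net, applyScaler(sc, d$x[sp$train, ])))
  expect_gte(m$auc, 0.99)
  # learning-rate schedule recorded in the history restarts on cycle
  expect_equal(net$history$lr[1], 9.36e-3)
  if (net$epochs >= 21) expect_equal(net$history$lr[21], 9.36e-3)
})

test_that("a validation set lacking a class is refused", {
  d <- separableData(60)
  net <- buildQ4Net(seed = 1)
  expect_error(
    trainQ4Net(net, d$x, d$y, d$x[d$y == 1, ], d$y[d$y == 1],
               trainConfig(seed = 1)),
    "validation set lacking a class")
})

test_that("training is deterministic given the seed (dropout 0, 1 epoch)", {
  d <- separableData(300)
  cfg <- trainConfig(dropout = 0, maxEpochs = 1L, seed = 5)
  run <- function() {
    net <- buildQ4Net(seed = 5)
    trainQ4Net(net, d$x, d$y, d$x[1:50, ], d$y[1:50], cfg)
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$params, n2$params)
  expect_identical(n1$history, n2$history)
})

test_that("five repeats produce five rows and a best model by val AUC", {
  d <- separableData(400, seed = 8)
  cfg <- trainConfig(maxEpochs = 25L)
  re <- repeatAndSelect(d$x, d$y, k = 5, config = cfg, seed = 3)
  expect_identical(nrow(re$perRepeat), 5L)
  expect_identical(re$best$repeatIndex, which.max(re$perRepeat$valAUC))
  expect_gte(re$means[["testAUC"]], 0.95)        # separable data
  # forcing identical seeds collapses the repeats
  re2 <- repeatAndSelect(d$x, d$y, k = 3, config = cfg, seeds = rep(4, 3))
  expect_identical(re2$perRepeat$testAUC,
                   rep(re2$perRepeat$testAUC[1], 3))
})
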