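#' Binary classification metric panel
#'
#' Computes the panel reported for the stress classifier: AUC by the
#' rank (Mann-Whitney) method, sensitivity and specificity at the
#' Youden-optimal threshold (or a fixed one), Gini = 2 AUC - 1 (the
#' exact identity, pre-rounding), log-loss with probabilities clamped
#' at 1e-15, and the mean squared error of probabilities against
#' labels.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param probabilities predicted probabilities.
#' @param thresholdRule `"youden"` picks the threshold maximizing
#'   sensitivity + specificity - 1 on these data; `"fixed"` uses
#'   `threshold`.
#' @param threshold operating threshold when `thresholdRule = "fixed"`.
#' @return list of class `"evalMetrics"`: `auc`, `sensitivity`,
#'   `specificity`, `gini`, `logLoss`, `mse`, `threshold`.
#' @examples
#' m <- evaluateBinary(c(0, 0, 1, 1), c(.1, .2, .8, .9))
#' m$auc    # 1
#' @export
evaluateBinary <- function(labels, probabilities,
                           thresholdRule = c("youden", "fixed"),
                           threshold = 0.5) {
  thresholdRule <- match.arg(thresholdRule)
  y <- as.integer(labels == 1)
  p <- as.numeric(probabilities)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(p)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  if (thresholdRule == "youden") {
    th <- sort(unique(p))
    sens <- vapply(th, function(t) mean(p[y == 1] >= t), numeric(1))
    spec <- vapply(th, function(t) mean(p[y == 0] < t), numeric(1))
    best <- which.max(sens + spec - 1)
    threshold <- th[best]
    sens <- sens[best]; spec <- spec[best]
  } else {
    sens <- mean(p[y == 1] >= threshold)
    spec <- mean(p[y == 0] < threshold)
  }
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  structure(list(auc = auc, sensitivity = sens, specificity = spec,
                 gini = 2 * auc - 1,
                 logLoss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
                 mse = mean((p - y)^2),
                 threshold = threshold),
            class = "evalMetrics")
}

#' @exportS3Method base::print
print.evalMetrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | sens %.3f | spec %.3f | Gini %.3f | log-loss %.3f | MSE %.3f (thr %.3f)\n",
    x$auc, x$sensitivity, x$specificity, x$gini, x$logLoss, x$mse,
    x$threshold))
  invisible(x)
}

#' Logistic-regression comparator
#'
#' Maximum-likelihood logistic fit on the same eight features as the
#' network, evaluated with the same metric panel. Perfect separation is
#' flagged and the fit falls back to a ridge-penalized logistic model.
#'
#' @param features numeric matrix or data.frame of predictors.
#' @param labels 0/1 outcome.
#' @param ridgeLambda penalty of the fallback fit.
#' @return list of class `"logisticFit"`: `coefficients`, `separation`
#'   (logical flag), `probabilities`, `metrics` (an `"evalMetrics"`),
#'   and `engine` (`"glm"` or `"glmnet-ridge"`).
#' @export
fitLogistic <- function(features, labels, ridgeLambda = 1e-2) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(labels == 1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  df <- data.frame(y = y, x, check.names = FALSE)
  sepWarned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarned <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- sepWarned && (!fit$converged ||
                              max(abs(coef(fit)[-1]), na.rm = TRUE) > 15)
  if (separation) {
    xr <- x
    if (ncol(xr) == 1L)           # glmnet requires >= 2 columns
      xr <- cbind(xr, `.pad` = 0)
    gn <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                         lambda = ridgeLambda, standardize = TRUE)
    prob <- as.numeric(predict(gn, newx = xr, type = "response"))
    cf <- as.numeric(coef(gn))
    names(cf) <- rownames(coef(gn))
    cf <- cf[names(cf) != ".pad"]
    engine <- "glmnet-ridge"
  } else {
    prob <- as.numeric(fitted(fit))
    cf <- coef(fit)
    engine <- "glm"
  }
  structure(list(coefficients = cf, separation = separation,
                 probabilities = prob,
                 metrics = evaluateBinary(y, prob),
                 engine = engine,
                 glm = if (!separation) fit else NULL),
            class = "logisticFit")
}

#' @exportS3Method base::print
print.logisticFit <- function(x, ...) {
  cat(sprintf("Logistic comparator (%s)%s\n", x$engine,
              if (x$separation) " [separation flagged]" else ""))
  print(x$metrics)
  invisible(x)
}

#' Five-repeat training with best-model selection
#'
#' Runs `k` independent split/scale/train/evaluate cycles with derived
#' seeds, reports the per-repeat and mean metric panels, and selects
#' the repeat with the highest validation AUC as the final model.
#'
#' @param features numeric matrix of the eight classifier inputs.
#' @param labels 0/1 top-quartile indicator.
#' @param k number of repeats (default 5).
#' @param config a [trainConfig()].
#' @param seed master seed; repeat r uses `seed + r` unless `seeds`
#'   is supplied.
#' @param seeds optional explicit length-`k` seed vector (identical
#'   seeds give identical repeats).
#' @return list of class `"repeatEval"`: `perRepeat` (data.frame of
#'   test metrics with a `set = "test"` panel plus train/val AUC),
#'   `means`, `best` (list with the selected `net`, `scaler`, `split`,
#'   `repeat` index), `k`.
#' @export
repeatAndSelect <- function(features, labels, k = 5L,
                            config = trainConfig(), seed = 1L,
                            seeds = NULL) {
  stopifnot(k >= 1)
  x <- as.matrix(features)
  y <- as.integer(labels == 1)
  if (is.null(seeds)) seeds <- seed + seq_len(k)
  stopifnot(length(seeds) == k)
  rows <- list(); runs <- list()
  for (r in seq_len(k)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    sp <- splitDataset(y, seed = cfg$seed)
    sc <- fitScaler(x[sp$train, , drop = FALSE])
    xt <- applyScaler(sc, x[sp$train, , drop = FALSE])
    xv <- applyScaler(sc, x[sp$validation, , drop = FALSE])
    xs <- applyScaler(sc, x[sp$test, , drop = FALSE])
    net <- buildQ4Net(seed = cfg$seed, leak = cfg$leak)
    net <- trainQ4Net(net, xt, y[sp$train], xv, y[sp$validation], cfg)
    mTr <- evaluateBinary(y[sp$train], predictQ4(net, xt))
    mVa <- evaluateBinary(y[sp$validation], predictQ4(net, xv))
    mTe <- evaluateBinary(y[sp$test], predictQ4(net, xs))
    rows[[r]] <- data.frame(repeatIndex = r, seed = seeds[r],
                            epochs = net$epochs,
                            trainAUC = mTr$auc, valAUC = mVa$auc,
                            testAUC = mTe$auc,
                            sensitivity = mTe$sensitivity,
                            specificity = mTe$specificity,
                            gini = mTe$gini, logLoss = mTe$logLoss,
                            mse = mTe$mse)
    runs[[r]] <- list(net = net, scaler = sc, split = sp,
                      testMetrics = mTe)
  }
  perRepeat <- do.call(rbind, rows)
  bestIx <- which.max(perRepeat$valAUC)
  metricCols <- setdiff(names(perRepeat), c("repeatIndex", "seed"))
  structure(list(perRepeat = perRepeat,
                 means = colMeans(perRepeat[metricCols]),
                 best = c(runs[[bestIx]], list(repeatIndex = bestIx)),
                 k = k),
            class = "repeatEval")
}

#' @exportS3Method base::print
print.repeatEval <- function(x, ...) {
  cat(sprintf("%d-repeat classifier evaluation (best repeat %d, val AUC %.3f)\n",
              x$k, x$best$repeatIndex,
              x$perRepeat$valAUC[x$best$repeatIndex]))
  print(x$perRepeat, row.names = FALSE)
  invisible(x)
}
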