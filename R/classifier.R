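#' Stratified train/validation/test split
#'
#' Partitions `n = length(labels)` indices into train, validation and
#' test sets sized by largest-remainder rounding of the ratios
#' (default 7:1:2), preserving the class proportions within one sample
#' per set. Reproducible under the seed.
#'
#' @param labels binary class labels (0/1) for all samples.
#' @param ratios length-3 positive weights for train/validation/test.
#' @param seed integer seed.
#' @return A list with integer index vectors `train`, `validation`,
#'   `test`: disjoint and exhaustive. A warning is raised when a set
#'   ends up without one of the classes (unavoidable at tiny n);
#'   [trainQ4Net()] then refuses such a validation set.
#' @examples
#' sp <- splitDataset(rep(0:1, 5), seed = 1)
#' lengths(sp)   # 7 1 2
#' @export
splitDataset <- function(labels, ratios = c(7, 1, 2), seed = 1L) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 samples to split")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  set.seed(as.integer(seed))
  sizes <- largestRemainder(n * ratios / sum(ratios))
  pos <- which(labels == 1)
  neg <- which(labels != 1)
  palloc <- largestRemainder(length(pos) * ratios / sum(ratios))
  # keep the per-class allocation inside the global set sizes
  over <- palloc > sizes
  while (any(over)) {
    i <- which(over)[1]
    j <- which.max(sizes - palloc)
    palloc[i] <- palloc[i] - 1L
    palloc[j] <- palloc[j] + 1L
    over <- palloc > sizes
  }
  nalloc <- sizes - palloc
  pos <- pos[sample.int(length(pos))]
  neg <- neg[sample.int(length(neg))]
  cutp <- cumsum(c(0, palloc))
  cutn <- cumsum(c(0, nalloc))
  sets <- lapply(1:3, function(s) {
    sort(c(pos[seq_len(palloc[s]) + cutp[s]],
           neg[seq_len(nalloc[s]) + cutn[s]]))
  })
  names(sets) <- c("train", "validation", "test")
  bad <- vapply(sets, function(ix) length(unique(labels[ix])) < 2L, logical(1))
  if (any(bad))
    warning("class absent from set(s): ",
            paste(names(sets)[bad], collapse = ", "))
  sets
}

largestRemainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  left <- round(sum(x)) - sum(fl)
  if (left > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' Min-max scaler fitted on the training set
#'
#' Stores per-feature training minima and maxima; the training set maps
#' into \[0, 1\] and validation/test sets are transformed with the same
#' coefficients (values outside \[0, 1\] are permitted, not clipped).
#' A constant training feature maps to 0 with a warning.
#'
#' @param x numeric matrix or data.frame of training features.
#' @return list of class `"scalerState"` with `min` and `max`.
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("training set is empty")
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  if (any(mx - mn <= 0))
    warning("constant training feature(s) map to 0: ",
            paste(colnames(x)[mx - mn <= 0], collapse = ", "))
  structure(list(min = mn, max = mx), class = "scalerState")
}

#' @rdname fitScaler
#' @param state a fitted `"scalerState"`.
#' @export
applyScaler <- function(state, x) {
  stopifnot(inherits(state, "scalerState"))
  x <- as.matrix(x)
  rng <- state$max - state$min
  rng[rng <= 0] <- Inf   # constant feature -> 0
  sweep(sweep(x, 2, state$min, "-"), 2, rng, "/")
}

#' The eight classifier features of a cohort table
#'
#' Non-paroxysmal AF, age, hypertension, diabetes, vascular disease,
#' heart failure, LVEF and E/Em — the non-invasive inputs of the
#' top-quartile stress classifier (mean LA voltage, an invasive
#' parameter, is deliberately not an input).
#'
#' @param cohort a cohort data.frame.
#' @return numeric matrix with 8 ordered columns.
#' @export
classifierFeatures <- function(cohort) {
  cols <- c("non_paroxysmal_af", "age", "hypertension", "diabetes",
            "vascular_disease", "heart_failure", "lvef", "e_em")
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("cohort lacks feature columns: ",
                         paste(miss, collapse = ", "))
  as.matrix(cohort[cols])
}

#' Cosine-annealed learning rate
#'
#' Restarting cosine schedule: within each cycle of `cycle` epochs the
#' rate decays from `lr0` as
#' \eqn{0.5\,lr_0 (1 + \cos(\pi\,t/\mathrm{cycle}))}; each cycle starts
#' again at `lr0`.
#'
#' @param epoch 1-based epoch number.
#' @param lr0 initial learning rate (default 9.36e-3).
#' @param cycle cycle length in epochs (default 20).
#' @return the learning rate for that epoch.
#' @export
cosineAnnealingRate <- function(epoch, lr0 = 9.36e-3, cycle = 20L) {
  phase <- ((epoch - 1) %% cycle) / cycle
  0.5 * lr0 * (1 + cos(pi * phase))
}

#' Training configuration for the Q4 classifier
#'
#' Defaults follow the published protocol: Adam with initial learning
#' rate 9.36e-3 and a 20-epoch cosine-annealing cycle, sigmoid
#' cross-entropy loss, class-stratified batches of 35, early stopping
#' when the validation loss has not improved for 10 epochs (best
#' weights restored), dropout 0.2.
#'
#' @param lr0 initial learning rate.
#' @param cycle cosine annealing cycle, epochs.
#' @param patience early-stopping patience, epochs.
#' @param batchSize mini-batch size.
#' @param maxEpochs hard epoch cap.
#' @param dropout dropout rate in the fully connected stacks.
#' @param leak LeakyReLU negative slope after the convolution.
#' @param bnMomentum running-statistics momentum of batch norm.
#' @param bnEps batch-norm variance floor.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return list of class `"trainConfig"`.
#' @export
trainConfig <- function(lr0 = 9.36e-3, cycle = 20L, patience = 10L,
                        batchSize = 35L, maxEpochs = 200L, dropout = 0.2,
                        leak = 0.2, bnMomentum = 0.9, bnEps = 1e-3,
                        seed = 1L) {
  structure(list(lr0 = lr0, cycle = as.integer(cycle),
                 patience = as.integer(patience),
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 dropout = dropout, leak = leak,
                 bnMomentum = bnMomentum, bnEps = bnEps,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Build the top-quartile stress network
#'
#' Fixed architecture: eight 3x1 convolution kernels (stride 1, no
#' padding, no pooling so no clinical feature is discarded), batch
#' norm, LeakyReLU, flatten (6 positions x 8 filters = 48), then two
#' fully connected stacks of 16 and 4 units (each batch norm, ReLU,
#' dropout) and a single sigmoid output unit. He-initialized weights;
#' deterministic given the seed.
#'
#' @param seed integer seed for weight initialization.
#' @param leak LeakyReLU negative slope.
#' @return list of class `"q4Net"` with elements `params`, `buffers`
#'   (batch-norm running statistics) and `arch`.
#' @examples
#' net <- buildQ4Net(seed = 1)
#' netParameterCount(net)   # 945
#' @export
buildQ4Net <- function(seed = 1L, leak = 0.2) {
  set.seed(as.integer(seed))
  he <- function(nr, nc, fanIn) matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)),
                                       nr, nc)
  params <- list(
    Wc = he(3, 8, 3), bc = numeric(8),
    g0 = rep(1, 8), be0 = numeric(8),
    W1 = he(48, 16, 48), b1 = numeric(16),
    g1 = rep(1, 16), be1 = numeric(16),
    W2 = he(16, 4, 16), b2 = numeric(4),
    g2 = rep(1, 4), be2 = numeric(4),
    W3 = he(4, 1, 4), b3 = numeric(1))
  buffers <- list(rm0 = numeric(8), rv0 = rep(1, 8),
                  rm1 = numeric(16), rv1 = rep(1, 16),
                  rm2 = numeric(4), rv2 = rep(1, 4))
  structure(list(params = params, buffers = buffers,
                 arch = list(leak = leak, nFeatures = 8L, nFilters = 8L,
                             kernel = 3L, fc = c(16L, 4L))),
            class = "q4Net")
}

#' Number of trainable parameters of a Q4 network
#' @param net a `"q4Net"`.
#' @return integer parameter count.
#' @export
netParameterCount <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

bnForward <- function(x, gamma, beta, rmean, rvar, eps, momentum,
                      training) {
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
    va <- pmax(va, 0)
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(sweep(x, 2, mu, "-"), 2, istd, "*")
  y <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xh = xh, istd = istd, rmean = rmean, rvar = rvar)
}

bnBackward <- function(dy, cache, gamma) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, "*")
  t1 <- sweep(dxh, 2, colMeans(dxh), "-")
  t2 <- cache$xh * matrix(colMeans(dxh * cache$xh), m, ncol(dy), byrow = TRUE)
  dx <- sweep(t1 - t2, 2, cache$istd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# windows of the 8-vector for the 3x1 convolution: (6n) x 3, block p = rows
# (p-1)n + 1..n
convWindows <- function(X) {
  n <- nrow(X)
  Xw <- matrix(0, 6 * n, 3)
  for (p in 1:6) Xw[(p - 1) * n + seq_len(n), ] <- X[, p:(p + 2)]
  Xw
}

q4Forward <- function(net, X, training = FALSE, dropout = 0) {
  p <- net$params; b <- net$buffers; a <- net$arch
  eps <- if (!is.null(net$bnEps)) net$bnEps else 1e-3
  mom <- if (!is.null(net$bnMomentum)) net$bnMomentum else 0.9
  n <- nrow(X)
  Xw <- convWindows(X)
  Z0 <- sweep(Xw %*% p$Wc, 2, p$bc, "+")
  bn0 <- bnForward(Z0, p$g0, p$be0, b$rm0, b$rv0, eps, mom, training)
  Y0 <- bn0$y
  A0 <- pmax(Y0, 0) + a$leak * pmin(Y0, 0)
  FF <- matrix(0, n, 48)
  for (q in 1:6) FF[, (q - 1) * 8 + 1:8] <- A0[(q - 1) * n + seq_len(n), ]
  Z1 <- sweep(FF %*% p$W1, 2, p$b1, "+")
  bn1 <- bnForward(Z1, p$g1, p$be1, b$rm1, b$rv1, eps, mom, training)
  A1 <- pmax(bn1$y, 0)
  D1 <- if (training && dropout > 0)
    matrix(rbinom(n * 16, 1, 1 - dropout), n, 16) / (1 - dropout)
  else matrix(1, n, 16)
  H1 <- A1 * D1
  Z2 <- sweep(H1 %*% p$W2, 2, p$b2, "+")
  bn2 <- bnForward(Z2, p$g2, p$be2, b$rm2, b$rv2, eps, mom, training)
  A2 <- pmax(bn2$y, 0)
  D2 <- if (training && dropout > 0)
    matrix(rbinom(n * 4, 1, 1 - dropout), n, 4) / (1 - dropout)
  else matrix(1, n, 4)
  H2 <- A2 * D2
  z <- drop(H2 %*% p$W3) + p$b3
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, logit = z,
       cache = list(X = X, Xw = Xw, bn0 = bn0, Y0 = Y0, FF = FF,
                    bn1 = bn1, Y1 = bn1$y, D1 = D1, H1 = H1,
                    bn2 = bn2, Y2 = bn2$y, D2 = D2, H2 = H2, n = n))
}

q4Backward <- function(net, fw, y) {
  p <- net$params; a <- net$arch; cc <- fw$cache
  n <- cc$n
  dz <- matrix((fw$prob - y) / n, n, 1)
  g <- list()
  g$W3 <- t(cc$H2) %*% dz
  g$b3 <- sum(dz)
  dH2 <- dz %*% t(p$W3)
  dA2 <- dH2 * cc$D2
  dY2 <- dA2 * (cc$Y2 > 0)
  bb2 <- bnBackward(dY2, cc$bn2, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  g$W2 <- t(cc$H1) %*% bb2$dx
  g$b2 <- colSums(bb2$dx)
  dH1 <- bb2$dx %*% t(p$W2)
  dA1 <- dH1 * cc$D1
  dY1 <- dA1 * (cc$Y1 > 0)
  bb1 <- bnBackward(dY1, cc$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  g$W1 <- t(cc$FF) %*% bb1$dx
  g$b1 <- colSums(bb1$dx)
  dFF <- bb1$dx %*% t(p$W1)
  dA0 <- matrix(0, 6 * n, 8)
  for (q in 1:6) dA0[(q - 1) * n + seq_len(n), ] <- dFF[, (q - 1) * 8 + 1:8]
  dY0 <- dA0 * ifelse(cc$Y0 > 0, 1, a$leak)
  bb0 <- bnBackward(dY0, cc$bn0, p$g0)
  g$g0 <- bb0$dgamma; g$be0 <- bb0$dbeta
  g$Wc <- t(cc$Xw) %*% bb0$dx
  g$bc <- colSums(bb0$dx)
  g[names(p)]
}

sigmoidCrossEntropy <- function(logit, y) {
  mean(pmax(logit, 0) - y * logit + log1p(exp(-abs(logit))))
}

# class-stratified mini-batches: positives and negatives are shuffled and
# spread over ceiling(n / batchSize) batches in proportion
shuffle <- function(x) x[sample.int(length(x))]

stratifiedBatches <- function(y, batchSize) {
  n <- length(y)
  nb <- max(1L, ceiling(n / batchSize))
  pos <- shuffle(which(y == 1))
  neg <- shuffle(which(y != 1))
  chunk <- function(ix) {
    if (!length(ix)) return(rep(list(integer()), nb))
    split(ix, factor(rep(seq_len(nb), length.out = length(ix)),
                     levels = seq_len(nb)))
  }
  cp <- chunk(pos); cn <- chunk(neg)
  lapply(seq_len(nb), function(b) shuffle(c(cp[[b]], cn[[b]])))
}

#' Train the Q4 network
#'
#' Adam optimization of the sigmoid cross-entropy loss with the
#' restarting cosine learning-rate schedule, class-stratified batches,
#' and early stopping on the validation loss with best-weights
#' restoration. Inputs must already be min-max scaled (see
#' [fitScaler()]).
#'
#' @param net a [buildQ4Net()] network.
#' @param xTrain,yTrain scaled training features (n x 8) and 0/1 labels.
#' @param xVal,yVal validation features and labels; the validation set
#'   must contain both classes.
#' @param config a [trainConfig()].
#' @return the trained network (best-validation weights), with a
#'   `history` data.frame (epoch, learning rate, train and validation
#'   loss) and `epochs` attached.
#' @export
trainQ4Net <- function(net, xTrain, yTrain, xVal, yVal,
                       config = trainConfig()) {
  stopifnot(inherits(net, "q4Net"), inherits(config, "trainConfig"))
  xTrain <- as.matrix(xTrain); xVal <- as.matrix(xVal)
  if (length(unique(yVal)) < 2L)
    stop("validation set lacking a class")
  if (length(unique(yTrain)) < 2L)
    stop("training set lacking a class")
  net$bnEps <- config$bnEps
  net$bnMomentum <- config$bnMomentum
  set.seed(config$seed)
  adam <- list(m = lapply(net$params, function(p) p * 0),
               v = lapply(net$params, function(p) p * 0), t = 0L)
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  stop_state <- earlyStopInit()
  bestParams <- net$params
  bestBuffers <- net$buffers
  hist <- list()
  for (epoch in seq_len(config$maxEpochs)) {
    lr <- cosineAnnealingRate(epoch, config$lr0, config$cycle)
    batches <- stratifiedBatches(yTrain, config$batchSize)
    epLoss <- 0
    for (bix in batches) {
      fw <- q4Forward(net, xTrain[bix, , drop = FALSE], training = TRUE,
                      dropout = config$dropout)
      net$buffers <- list(rm0 = fw$cache$bn0$rmean, rv0 = fw$cache$bn0$rvar,
                          rm1 = fw$cache$bn1$rmean, rv1 = fw$cache$bn1$rvar,
                          rm2 = fw$cache$bn2$rmean, rv2 = fw$cache$bn2$rvar)
      gr <- q4Backward(net, fw, yTrain[bix])
      adam$t <- adam$t + 1L
      for (nm in names(net$params)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * gr[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * gr[[nm]]^2
        mh <- adam$m[[nm]] / (1 - beta1^adam$t)
        vh <- adam$v[[nm]] / (1 - beta2^adam$t)
        net$params[[nm]] <- net$params[[nm]] - lr * mh / (sqrt(vh) + aeps)
      }
      epLoss <- epLoss + sigmoidCrossEntropy(fw$logit, yTrain[bix]) *
        length(bix)
    }
    valLoss <- sigmoidCrossEntropy(
      q4Forward(net, xVal, training = FALSE)$logit, yVal)
    hist[[epoch]] <- c(epoch = epoch, lr = lr,
                       trainLoss = epLoss / length(yTrain),
                       valLoss = valLoss)
    stop_state <- earlyStopUpdate(stop_state, valLoss, config$patience)
    if (stop_state$improved) {
      bestParams <- net$params
      bestBuffers <- net$buffers
    }
    if (stop_state$stop) break
  }
  net$params <- bestParams
  net$buffers <- bestBuffers
  net$history <- as.data.frame(do.call(rbind, hist))
  net$epochs <- nrow(net$history)
  net
}

#' Early-stopping bookkeeping
#'
#' Pure helper implementing the patience rule: training stops once the
#' monitored loss has failed to improve (strictly) for `patience`
#' consecutive updates; the best value seen so far is tracked so the
#' caller can restore best weights.
#'
#' @return `earlyStopInit()` returns a fresh state;
#'   `earlyStopUpdate(state, loss, patience)` returns the state with
#'   fields `best`, `wait`, `improved` and `stop`.
#' @export
earlyStopInit <- function() {
  list(best = Inf, wait = 0L, improved = FALSE, stop = FALSE)
}

#' @rdname earlyStopInit
#' @param state state list from a previous call.
#' @param loss monitored (validation) loss of this epoch.
#' @param patience non-improving epochs tolerated before stopping.
#' @export
earlyStopUpdate <- function(state, loss, patience) {
  if (loss < state$best) {
    state$best <- loss
    state$wait <- 0L
    state$improved <- TRUE
  } else {
    state$wait <- state$wait + 1L
    state$improved <- FALSE
  }
  state$stop <- state$wait >= patience
  state
}

#' Predict top-quartile stress probabilities
#'
#' Forward pass in evaluation mode (dropout off, batch-norm running
#' statistics frozen).
#'
#' @param net a trained `"q4Net"`.
#' @param x scaled feature matrix (n x 8).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictQ4 <- function(net, x) {
  stopifnot(inherits(net, "q4Net"))
  q4Forward(net, as.matrix(x), training = FALSE)$prob
}
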