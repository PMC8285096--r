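#' Multi-class Otsu thresholds
#'
#' Finds the `nClasses - 1` strictly increasing thresholds that maximize
#' the between-class variance of a histogram (the multi-level extension
#' of Otsu's criterion), by exact dynamic programming over the bin
#' boundaries. Used to separate background, wall and contrast-filled
#' lumen intensities on CT-like volumes.
#'
#' @param values raw intensity values (a histogram is built with
#'   `nBins` equal-width bins); alternatively supply `counts` and
#'   `mids` directly.
#' @param nClasses number of intensity classes (>= 2).
#' @param nBins number of histogram bins when `values` is given.
#' @param counts,mids histogram bin counts and bin centres (equal-width
#'   bins assumed for the returned threshold placement).
#' @return numeric vector of `nClasses - 1` thresholds, strictly
#'   increasing, each placed at the upper edge of the last bin of its
#'   class.
#' @examples
#' x <- c(rnorm(300, 0, 1), rnorm(300, 100, 1))
#' th <- multiOtsuThresholds(x, nClasses = 2)
#' th > 0 && th < 100
#' @export
multiOtsuThresholds <- function(values = NULL, nClasses = 3, nBins = 256,
                                counts = NULL, mids = NULL) {
  if (nClasses < 2) stop("nClasses must be at least 2")
  if (is.null(counts)) {
    values <- values[is.finite(values)]
    if (length(unique(values)) < 2L)
      stop("degenerate histogram: all intensities identical")
    rng <- range(values)
    edges <- seq(rng[1], rng[2], length.out = nBins + 1)
    counts <- tabulate(pmin(findInterval(values, edges,
                                         rightmost.closed = TRUE), nBins),
                       nBins)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
  } else {
    if (length(counts) != length(mids))
      stop("counts and mids must have equal length")
    if (sum(counts > 0) < 2L)
      stop("degenerate histogram: all intensities identical")
  }
  if (sum(counts > 0) < nClasses)
    stop("histogram has fewer non-empty bins (", sum(counts > 0),
         ") than classes (", nClasses, ")")

  B <- length(counts)
  w <- counts / sum(counts)
  W <- c(0, cumsum(w))              # cumulative weight up to bin b
  M <- c(0, cumsum(w * mids))       # cumulative first moment
  score <- function(a, b) {         # class = bins (a+1)..b, 0-based prefix
    ww <- W[b + 1] - W[a + 1]
    if (ww <= 0) return(-Inf)
    (M[b + 1] - M[a + 1])^2 / ww
  }
  # f[c, b]: best sum of class scores using c classes over bins 1..b
  f <- matrix(-Inf, nClasses, B)
  arg <- matrix(NA_integer_, nClasses, B)
  for (b in 1:B) f[1, b] <- score(0, b)
  for (cc in 2:nClasses) {
    for (b in cc:B) {
      best <- -Inf; bi <- NA_integer_
      for (a in (cc - 1):(b - 1)) {
        v <- f[cc - 1, a] + score(a, b)
        if (v > best) { best <- v; bi <- a }
      }
      f[cc, b] <- best; arg[cc, b] <- bi
    }
  }
  if (!is.finite(f[nClasses, B]))
    stop("no feasible threshold placement for ", nClasses, " classes")
  bounds <- integer(nClasses - 1)
  b <- B
  for (cc in nClasses:2) {
    bounds[cc - 1] <- arg[cc, b]
    b <- arg[cc, b]
  }
  half <- if (B > 1) (mids[2] - mids[1]) / 2 else 0
  th <- mids[bounds] + half
  if (any(diff(th) <= 0)) stop("thresholds are not strictly increasing")
  th
}
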