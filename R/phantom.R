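#' Generate a shell phantom with analytically known wall thickness
#'
#' Builds a CT-like intensity volume containing a wall of known
#' geometry, together with its exact voxel labels and per-voxel true
#' thickness. Three shapes are available:
#'
#' * `"concentric"` — spherical shell between radii `rInner` and
#'   `rOuter`; the true thickness is `rOuter - rInner` everywhere.
#' * `"eccentric"` — inner sphere displaced by `offset` mm along x; the
#'   true thickness, measured along rays from the inner centre, ranges
#'   over `[rOuter - rInner - offset, rOuter - rInner + offset]`.
#' * `"slab"` — a flat wall of thickness `slabGap` mm normal to z, with
#'   "lumen" below and background above.
#'
#' Intensities follow a piecewise-constant model (lumen bright as in
#' contrast CT, wall intermediate, background dark) plus optional
#' additive Gaussian noise.
#'
#' @param shape one of `"concentric"`, `"eccentric"`, `"slab"`.
#' @param rInner,rOuter inner/outer radii in mm (sphere shapes).
#' @param offset inner-centre displacement in mm (eccentric only); must
#'   be smaller than `rOuter - rInner`.
#' @param slabGap slab thickness in mm.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param dims grid dimensions; by default just large enough to contain
#'   the shell plus a 2-voxel margin.
#' @param lumenHU,wallHU,backgroundHU class mean intensities.
#' @param noiseSD additive Gaussian noise standard deviation.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return A list with elements `volume` ([LAVolume-class]), `mask`
#'   (ground-truth [WallMask-class]), `thickness` (true per-voxel
#'   thickness array, NA off the wall), and `meanThickness` (true mean
#'   over wall voxels, mm).
#' @examples
#' ph <- shellPhantom("concentric", rInner = 5, rOuter = 7,
#'                    spacing = c(1, 1, 1))
#' ph$meanThickness   # exactly 2
#' @export
shellPhantom <- function(shape = c("concentric", "eccentric", "slab"),
                         rInner = 10, rOuter = 12, offset = 1, slabGap = 3,
                         spacing = c(0.5, 0.5, 0.5), dims = NULL,
                         lumenHU = 300, wallHU = 100, backgroundHU = 0,
                         noiseSD = 0, seed = 1L) {
  shape <- match.arg(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (shape != "slab") {
    if (!(rOuter > rInner && rInner > 0))
      stop("need rOuter > rInner > 0")
    if (shape == "eccentric" && !(offset >= 0 && offset < rOuter - rInner))
      stop("offset must be smaller than the wall thickness rOuter - rInner")
  } else if (slabGap <= 0) stop("slabGap must be positive")

  if (is.null(dims)) {
    dims <- if (shape == "slab") {
      c(ceiling(4 * slabGap / spacing[1:2]), ceiling(3 * slabGap / spacing[3]) + 4L)
    } else {
      ceiling(2 * rOuter / spacing) + 5L
    }
  }
  dims <- as.integer(dims)
  # voxel-centre physical coordinates
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]

  labels <- array(0L, dims)
  thickness <- array(NA_real_, dims)

  if (shape == "slab") {
    z0 <- cz[3]  # wall occupies [z0, z0 + slabGap)
    zArr <- array(rep(cz, each = dims[1] * dims[2]), dims)
    lumen <- zArr < z0 - 1e-9
    wall <- !lumen & zArr < z0 + slabGap - 1e-9
    labels[lumen] <- 1L
    labels[wall] <- 2L
    thickness[wall] <- slabGap
  } else {
    centre <- (dims - 1) / 2 * spacing
    if (any(centre < rOuter + 2 * spacing))
      stop("shell does not fit in the grid with a 2-voxel margin")
    dx2 <- outer((cx - centre[1])^2, (cy - centre[2])^2, "+")
    r <- sqrt(outer(c(dx2), (cz - centre[3])^2, "+"))
    dim(r) <- dims
    if (shape == "concentric") {
      lumen <- r < rInner
      wall <- !lumen & r < rOuter
      labels[lumen] <- 1L
      labels[wall] <- 2L
      thickness[wall] <- rOuter - rInner
    } else {
      innerC <- centre + c(offset, 0, 0)
      dxi2 <- outer((cx - innerC[1])^2, (cy - innerC[2])^2, "+")
      ri <- sqrt(outer(c(dxi2), (cz - innerC[3])^2, "+"))
      dim(ri) <- dims
      lumen <- ri < rInner
      wall <- !lumen & r < rOuter
      labels[lumen] <- 1L
      labels[wall] <- 2L
      # thickness along the ray from the inner centre through the voxel:
      # t(u) = -offset*u_x + sqrt(rOuter^2 - offset^2 (1 - u_x^2)) - rInner
      xArr <- array(rep(cx, times = dims[2] * dims[3]), dims)
      ux <- (xArr - innerC[1]) / pmax(ri, 1e-12)
      tth <- -offset * ux + sqrt(rOuter^2 - offset^2 * (1 - ux^2)) - rInner
      thickness[wall] <- tth[wall]
    }
  }

  intens <- array(backgroundHU, dims)
  intens[labels == 1L] <- lumenHU
  intens[labels == 2L] <- wallHU
  if (noiseSD > 0) {
    set.seed(as.integer(seed))
    intens <- intens + array(rnorm(prod(dims), sd = noiseSD), dims)
  }

  list(volume = LAVolume(intens, spacing),
       mask = WallMask(labels, spacing),
       thickness = thickness,
       meanThickness = mean(thickness[labels == 2L]))
}
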