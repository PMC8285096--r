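#' Voxelized scalar volume with anisotropic spacing
#'
#' A 3-D intensity grid (CT-like, Hounsfield-unit scale) together with
#' its voxel spacing in mm. Voxel centres sit at 0-based index times
#' spacing; all lengths reported by the package are in mm.
#'
#' @slot voxels numeric 3-D array of intensities.
#' @slot spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @export
setClass("LAVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Labeled wall mask with boundary tags
#'
#' Per-voxel labels (0 = background, 1 = lumen, 2 = wall) plus logical
#' arrays tagging endocardial-adjacent (6-adjacent to lumen) and
#' epicardial-adjacent (6-adjacent to background) wall voxels.
#'
#' @slot labels integer 3-D array with values in {0, 1, 2}.
#' @slot endo,epi logical 3-D arrays tagging boundary wall voxels.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("WallMask",
  representation(labels = "array", endo = "array", epi = "array",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@labels %in% 0:2))
      msg <- c(msg, "labels must be 0 (background), 1 (lumen) or 2 (wall)")
    d <- dim(object@labels)
    if (!identical(d, dim(object@endo)) || !identical(d, dim(object@epi)))
      msg <- c(msg, "endo/epi arrays must match label dimensions")
    if (any(object@endo & object@labels != 2L) ||
        any(object@epi & object@labels != 2L))
      msg <- c(msg, "boundary tags must lie on wall voxels")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (length(msg)) msg else TRUE
  }
)

#' Harmonic potential over the wall
#'
#' Solution of the discrete Laplace equation on the wall voxels with
#' Dirichlet data endocardium = 0, epicardium = 1 (stored on the full
#' grid: lumen voxels 0, background voxels 1). By the discrete maximum
#' principle the potential lies in \[0, 1\].
#'
#' @slot potential numeric 3-D array over the full grid.
#' @slot mask the [WallMask-class] the equation was solved on.
#' @slot residual max absolute Gauss-Seidel update of the final sweep.
#' @slot iterations number of SOR sweeps performed.
#' @slot converged logical.
#' @export
setClass("PotentialField",
  representation(potential = "array", mask = "WallMask",
                 residual = "numeric", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@potential), dim(object@mask@labels)))
      msg <- c(msg, "potential must match mask dimensions")
    w <- object@mask@labels == 2L
    if (any(object@potential[w] < -1e-9 | object@potential[w] > 1 + 1e-9))
      msg <- c(msg, "wall potential must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Per-voxel streamline thickness and its mean
#'
#' @slot thickness numeric 3-D array, mm; NA outside the wall and at
#'   flagged voxels.
#' @slot meanThickness unweighted mean over non-flagged wall voxels, mm.
#' @slot flagged logical 3-D array of wall voxels excluded from the mean
#'   (flat gradient, step cap, or grid exit).
#' @slot diagnostics list: step size, flagged fraction, termination
#'   reason counts, mean Euler step count.
#' @export
setClass("ThicknessResult",
  representation(thickness = "array", meanThickness = "numeric",
                 flagged = "array", diagnostics = "list"),
  validity = function(object) {
    v <- object@thickness[!is.na(object@thickness)]
    if (length(v) && any(v <= 0)) "thickness values must be positive" else TRUE
  }
)

#' Construct an LAVolume
#'
#' @param voxels numeric 3-D array of intensities.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return An [LAVolume-class] object.
#' @examples
#' v <- LAVolume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' voxelSpacing(v)
#' @export
LAVolume <- function(voxels, spacing = c(1, 1, 1)) {
  new("LAVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a WallMask from a label array
#'
#' Boundary tags are derived from 6-adjacency: a wall voxel is
#' endocardial if 6-adjacent to lumen and epicardial if 6-adjacent to
#' background.
#'
#' @param labels integer 3-D array: 0 background, 1 lumen, 2 wall.
#' @param spacing voxel spacing in mm.
#' @return A [WallMask-class] object.
#' @export
WallMask <- function(labels, spacing = c(1, 1, 1)) {
  labels <- array(as.integer(labels), dim(labels))
  d <- dim(labels)
  wall <- labels == 2L
  endo <- wall & adjacent6(labels == 1L)
  epi  <- wall & adjacent6(labels == 0L)
  new("WallMask", labels = labels,
      endo = array(endo, d), epi = array(epi, d),
      spacing = as.numeric(spacing))
}

# TRUE where a voxel is 6-adjacent to any TRUE voxel of `mask`
adjacent6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shift <- function(m, ax, by) {
    r <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- 2:n;       src[[ax]] <- 1:(n - 1) }
    else        { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- out | shift(mask, ax, by)
  out
}
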