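#' @name accessors
#' @title Accessors for the imaging classes
#'
#' @description Slot access for [LAVolume-class], [WallMask-class],
#' [PotentialField-class] and [ThicknessResult-class] objects.
#'
#' @param object an object of the relevant class.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("wallLabels", function(object) standardGeneric("wallLabels"))
#' @rdname accessors
#' @export
setGeneric("endoBoundary", function(object) standardGeneric("endoBoundary"))
#' @rdname accessors
#' @export
setGeneric("epiBoundary", function(object) standardGeneric("epiBoundary"))
#' @rdname accessors
#' @export
setGeneric("potentialValues", function(object) standardGeneric("potentialValues"))
#' @rdname accessors
#' @export
setGeneric("solverResidual", function(object) standardGeneric("solverResidual"))
#' @rdname accessors
#' @export
setGeneric("solverIterations", function(object) standardGeneric("solverIterations"))
#' @rdname accessors
#' @export
setGeneric("thicknessValues", function(object) standardGeneric("thicknessValues"))
#' @rdname accessors
#' @export
setGeneric("meanThickness", function(object) standardGeneric("meanThickness"))
#' @rdname accessors
#' @export
setGeneric("flaggedVoxels", function(object) standardGeneric("flaggedVoxels"))

#' @rdname accessors
setMethod("voxelData", "LAVolume", function(object) object@voxels)
#' @rdname accessors
setMethod("voxelSpacing", "LAVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "WallMask", function(object) object@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "PotentialField", function(object) object@mask@spacing)
#' @rdname accessors
setMethod("wallLabels", "WallMask", function(object) object@labels)
#' @rdname accessors
setMethod("wallLabels", "PotentialField", function(object) object@mask@labels)
#' @rdname accessors
setMethod("endoBoundary", "WallMask", function(object) object@endo)
#' @rdname accessors
setMethod("epiBoundary", "WallMask", function(object) object@epi)
#' @rdname accessors
setMethod("potentialValues", "PotentialField", function(object) object@potential)
#' @rdname accessors
setMethod("solverResidual", "PotentialField", function(object) object@residual)
#' @rdname accessors
setMethod("solverIterations", "PotentialField", function(object) object@iterations)
#' @rdname accessors
setMethod("thicknessValues", "ThicknessResult", function(object) object@thickness)
#' @rdname accessors
setMethod("meanThickness", "ThicknessResult", function(object) object@meanThickness)
#' @rdname accessors
setMethod("flaggedVoxels", "ThicknessResult", function(object) object@flagged)

setMethod("show", "LAVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LAVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "WallMask", function(object) {
  tab <- tabulate(object@labels + 1L, 3L)
  cat(sprintf(
    "WallMask: %s voxels | background %d, lumen %d, wall %d\n",
    paste(dim(object@labels), collapse = " x "), tab[1], tab[2], tab[3]))
  cat(sprintf("  boundary tags: endo %d, epi %d\n",
              sum(object@endo), sum(object@epi)))
})

setMethod("show", "PotentialField", function(object) {
  w <- object@mask@labels == 2L
  cat(sprintf(
    "PotentialField on %d wall voxels: range [%.4f, %.4f]\n",
    sum(w), min(object@potential[w]), max(object@potential[w])))
  cat(sprintf("  %d iterations, residual %.3g, converged: %s\n",
              object@iterations, object@residual, object@converged))
})

setMethod("show", "ThicknessResult", function(object) {
  cat(sprintf(
    "ThicknessResult: mean %.4g mm over %d voxels (%.1f%% flagged)\n",
    object@meanThickness, sum(!is.na(object@thickness)),
    100 * object@diagnostics$flaggedFraction))
})
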