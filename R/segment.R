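#' Segment the atrial wall from an intensity volume
#'
#' Three-class multi-Otsu thresholding of the intensity histogram
#' separates background, wall and contrast-bright lumen. The lumen is
#' taken as the largest 26-connected bright component; the wall-class
#' mask is cleaned by morphological closing then opening (6-neighbour
#' structuring element, radii in voxels) and restricted to the
#' 26-connected components adjacent to the lumen. Wall voxels are then
#' tagged endocardial (6-adjacent to lumen) or epicardial (6-adjacent
#' to background).
#'
#' @param volume an [LAVolume-class].
#' @param nBins histogram bins for the threshold search.
#' @param closingRadius,openingRadius morphology radii in voxels
#'   (0 disables the step).
#' @param checkClosed if TRUE, fail when the wall is not closed (some
#'   lumen voxel touches background directly).
#' @return A [WallMask-class].
#' @export
segmentWall <- function(volume, nBins = 256, closingRadius = 1,
                        openingRadius = 1, checkClosed = TRUE) {
  stopifnot(is(volume, "LAVolume"))
  v <- voxelData(volume)
  d <- dim(v)
  if (length(unique(as.vector(v))) < 3L ||
      diff(range(v)) < .Machine$double.eps^0.5)
    stop("no lumen component found: volume has a single intensity class")
  th <- multiOtsuThresholds(as.vector(v), nClasses = 3, nBins = nBins)

  bright <- v >= th[2]
  if (!any(bright)) stop("no lumen component found above the upper threshold")
  comp <- array(label_components_cpp(as.vector(bright), d, 26L), d)
  sizes <- tabulate(comp[comp > 0])
  lumen <- comp == which.max(sizes)

  # close the solid (lumen + wall-class) region so that noise pinholes
  # through the wall are filled, then carve the wall out of it
  solid <- (v >= th[1]) | lumen
  solid <- morph3(solid, d, closingRadius, "closing")
  wallCand <- solid & !lumen
  wallCand <- morph3(wallCand, d, openingRadius, "opening")
  wallCand <- wallCand & !lumen
  if (!any(wallCand)) stop("no wall voxels found adjacent to the lumen")

  wcomp <- array(label_components_cpp(as.vector(wallCand), d, 26L), d)
  nearLumen <- array(binary_dilate_cpp(as.vector(lumen), d, 6L), d)
  keep <- unique(wcomp[wcomp > 0 & nearLumen])
  wall <- wcomp > 0 & wcomp %in% keep
  if (!any(wall)) stop("no wall voxels found adjacent to the lumen")

  labels <- array(0L, d)
  labels[lumen] <- 1L
  labels[wall] <- 2L
  mask <- WallMask(labels, voxelSpacing(volume))

  if (checkClosed) {
    bg <- labels == 0L
    leak <- lumen & adjacent6(bg)
    if (any(leak))
      stop("wall is not closed: ", sum(leak),
           " lumen voxels touch background directly")
  }
  mask
}

# radius-fold closing/opening with the 6-neighbour structuring element
morph3 <- function(mask, d, radius, op = c("closing", "opening")) {
  op <- match.arg(op)
  if (radius <= 0) return(mask)
  m <- as.vector(mask)
  first <- if (op == "closing") binary_dilate_cpp else binary_erode_cpp
  second <- if (op == "closing") binary_erode_cpp else binary_dilate_cpp
  for (i in seq_len(radius)) m <- first(m, d, 6L)
  for (i in seq_len(radius)) m <- second(m, d, 6L)
  array(m, d)
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return the Dice coefficient 2|A∩B| / (|A| + |B|).
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
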