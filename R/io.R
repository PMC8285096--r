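#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the voxel spacing (mm) in the
#' header pixdim.
#'
#' @param volume an [LAVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns an [LAVolume-class].
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "LAVolume"))
  img <- RNifti::asNifti(voxelData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  LAVolume(array(as.numeric(img), dim(img)), spacing = sp)
}

# deterministic config fingerprint (djb2 over the deparsed object)
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 4294967296
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4),
         format(as.hexmode(as.integer(h %% 65536)), width = 4))
}

# per-stage seed derived from the master seed by a fixed counter scheme
stageSeed <- function(masterSeed, counter) {
  as.integer((as.numeric(masterSeed) * 101 + counter * 9973) %% 2147483647)
}
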