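#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti that keep the package's grid convention
#' (0-based voxel indices, RAS mm, affine stored in the sform) intact.
#' `readVolume()` returns the data array together with the [VolumeGrid-class]
#' recovered from the header; `writeVolume()` accepts a raw array, a
#' [BrainMask-class]/[SeedMask-class] (written as 0/1), a
#' [ProbabilityMap-class] or a [GroupNetworkMap-class] (its binary layer).
#' Data are stored as float64 so that written artefacts round-trip exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x object to write.
#' @param grid grid to stamp into the header (taken from `x` when it
#'   carries one).
#' @return `readVolume()`: list with `values` (array) and `grid`.
#'   `writeVolume()`: the path, invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid <- new("VolumeGrid", dim = as.integer(dim(img)[1:3]),
              affine = matrix(as.numeric(aff), 4, 4))
  list(values = as.array(img), grid = grid)
}

#' @rdname readVolume
#' @export
writeVolume <- function(x, path, grid = NULL) {
  if (is(x, "BrainMask") || is(x, "SeedMask")) {
    grid <- x@grid; arr <- array(as.numeric(x@values), gridDim(grid))
  } else if (is(x, "ProbabilityMap")) {
    grid <- x@grid; arr <- x@values
  } else if (is(x, "GroupNetworkMap")) {
    grid <- x@grid; arr <- array(as.numeric(x@binary), gridDim(grid))
  } else if (is(x, "CanonicalAtlas")) {
    grid <- x@grid; arr <- array(as.numeric(x@labels), gridDim(grid))
  } else {
    if (is.null(grid)) stop("grid is required when writing a raw array")
    arr <- x
  }
  img <- RNifti::asNifti(arr)
  aff <- structure(gridAffine(grid), code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, structure(gridAffine(grid), code = 0L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a 4-D BOLD series as NIfTI-1
#'
#' The repetition time is taken from the header's time-axis pixdim unless
#' overridden; writing stamps it back.
#'
#' @param path NIfTI file path.
#' @param trSeconds repetition time override (seconds); mandatory when the
#'   header carries none.
#' @param bold a [Bold4D-class].
#' @return `readBold()`: a [Bold4D-class]. `writeBold()`: the path,
#'   invisibly.
#' @export
readBold <- function(path, trSeconds = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4-D NIfTI volume")
  hdr <- RNifti::niftiHeader(img)
  if (is.null(trSeconds)) {
    trSeconds <- hdr$pixdim[5]
    if (!is.finite(trSeconds) || trSeconds <= 0)
      stop("header has no usable TR; pass trSeconds explicitly")
  }
  aff <- RNifti::xform(img)
  grid <- new("VolumeGrid", dim = as.integer(dim(img)[1:3]),
              affine = matrix(as.numeric(aff), 4, 4))
  bold4D(as.array(img), grid, trSeconds)
}

#' @rdname readBold
#' @export
writeBold <- function(bold, path) {
  img <- RNifti::asNifti(boldArray(bold))
  img$pixdim[5] <- bold@trSeconds
  RNifti::`sform<-`(img, structure(gridAffine(bold), code = 2L)) -> img
  RNifti::`qform<-`(img, structure(gridAffine(bold), code = 0L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a rigid-body motion parameter file
#'
#' Whitespace-delimited text, one row per volume, six columns: three
#' translations (mm) then three rotations. Rotations are radians by
#' default (the SPM realignment convention); set `rotationUnits =
#' "degrees"` for tools that emit degrees.
#'
#' @param path text file path.
#' @param rotationUnits `"radians"` (default) or `"degrees"`.
#' @return Numeric matrix, n-by-6, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z` (rotations radians).
#' @export
readMotionFile <- function(path, rotationUnits = c("radians", "degrees")) {
  rotationUnits <- match.arg(rotationUnits)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion file must have exactly 6 columns, got ", ncol(m))
  if (rotationUnits == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  storage.mode(m) <- "double"
  m
}
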