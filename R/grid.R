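#' Construct a VolumeGrid
#'
#' @param dim integer(3) array dimensions.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices, RAS mm).
#'   Defaults to an isotropic grid of `voxelMm` spacing centred on the
#'   origin, the usual layout for a standard-space analysis grid.
#' @param voxelMm isotropic voxel size used when `affine` is missing.
#' @return A [VolumeGrid-class] object.
#' @examples
#' g <- volumeGrid(c(24, 24, 24), voxelMm = 3)
#' voxelSizes(g)
#' @export
volumeGrid <- function(dim, affine = NULL, voxelMm = 3) {
  dim <- as.integer(dim)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelMm, 3), 1))
    # centre of the grid maps (approximately) to the origin
    affine[1:3, 4] <- -voxelMm * (dim - 1) / 2
  }
  new("VolumeGrid", dim = dim, affine = affine)
}

#' Grid accessors
#'
#' `gridDim()` and `gridAffine()` expose the lattice geometry;
#' `voxelSizes()` gives the per-axis spacing in mm and `voxelVolume()` the
#' volume of one voxel in mm^3; `nVoxels()` counts lattice points.
#'
#' @param x an object carrying a grid (a [VolumeGrid-class] or any class
#'   with a `grid` slot).
#' @return Dimensions, affine, spacings, scalar volume, or voxel count.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname grid-accessors
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

setMethod("gridDim", "VolumeGrid", function(x) x@dim)
setMethod("gridAffine", "VolumeGrid", function(x) x@affine)

for (.cls in c("BrainMask", "SeedMask", "Bold4D", "GroupNetworkMap",
               "ProbabilityMap", "CanonicalAtlas")) {
  setMethod("gridDim", .cls, function(x) x@grid@dim)
  setMethod("gridAffine", .cls, function(x) x@grid@affine)
}

#' @rdname grid-accessors
#' @export
voxelSizes <- function(x) {
  a <- gridAffine(x)
  sqrt(colSums(a[1:3, 1:3]^2))
}

#' @rdname grid-accessors
#' @export
voxelVolume <- function(x) abs(det(gridAffine(x)[1:3, 1:3]))

#' @rdname grid-accessors
#' @export
nVoxels <- function(x) prod(gridDim(x))

theGrid <- function(x) if (is(x, "VolumeGrid")) x else x@grid

sameGrid <- function(a, b, tol = 1e-6) {
  ga <- theGrid(a); gb <- theGrid(b)
  identical(ga@dim, gb@dim) && all(abs(ga@affine - gb@affine) < tol)
}

stopifnotSameGrid <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(what, " are not on the same grid (dim/affine mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' Convert between mm and voxel coordinates
#'
#' `mmToVoxel()` applies the inverse grid affine and rounds each component
#' to the nearest integer, halves away from zero. The result is a 0-based
#' voxel index and may fall outside the grid; callers decide how to treat
#' out-of-bounds indices (peak screening treats them as out-of-mask).
#' `voxelToMm()` maps 0-based voxel indices to world mm.
#'
#' @param mm numeric vector of 3 mm coordinates, or an n-by-3 matrix.
#' @param vox numeric vector of 3 voxel indices (0-based), or n-by-3 matrix.
#' @param grid a [VolumeGrid-class].
#' @return An n-by-3 matrix (or length-3 vector for vector input).
#' @examples
#' g <- volumeGrid(c(61, 73, 61), affine = {
#'   a <- diag(c(3, 3, 3, 1)); a[1:3, 4] <- c(-90, -126, -72); a
#' })
#' mmToVoxel(c(0, 0, 0), g)   # -> 30 42 24
#' @export
mmToVoxel <- function(mm, grid) {
  mm <- rbind(mm)
  vox <- t(solve(grid@affine, t(cbind(mm, 1))))[, 1:3, drop = FALSE]
  out <- sign(vox) * floor(abs(vox) + 0.5)   # half away from zero
  if (nrow(out) == 1L) out[1, ] else out
}

#' @rdname mmToVoxel
#' @export
voxelToMm <- function(vox, grid) {
  vox <- rbind(vox)
  out <- t(grid@affine %*% t(cbind(vox, 1)))[, 1:3, drop = FALSE]
  if (nrow(out) == 1L) out[1, ] else out
}

inBounds <- function(vox, grid) {
  vox <- rbind(vox)
  apply(vox, 1L, function(v) all(v >= 0) && all(v <= grid@dim - 1L))
}

# linear (column-major) index of 0-based voxel triplets
voxelIndex <- function(vox, grid) {
  vox <- rbind(vox)
  d <- grid@dim
  as.integer(1 + vox[, 1] + d[1] * (vox[, 2] + d[2] * vox[, 3]))
}

setMethod("show", "VolumeGrid", function(object) {
  vs <- voxelSizes(object)
  cat(sprintf("VolumeGrid: %s voxels, spacing %s mm\n",
              paste(object@dim, collapse = " x "),
              paste(signif(vs, 4), collapse = " x ")))
})
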