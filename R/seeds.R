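#' Build a spherical ROI on a grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its
#' centre (in mm, via the grid affine) to `centerMm` is at most
#' `radiusMm` (closed ball on voxel centres, the common neuroimaging
#' convention). Voxels outside the grid bounds are simply not
#' represented; a sphere lying entirely outside the grid yields an empty
#' volume with a warning.
#'
#' @param centerMm length-3 mm coordinate of the sphere centre.
#' @param radiusMm positive radius in mm.
#' @param grid a [VolumeGrid-class].
#' @return Logical array on the grid.
#' @examples
#' g <- volumeGrid(c(15, 15, 15), voxelMm = 3)
#' sum(buildSphere(voxelToMm(c(7, 7, 7), g), 4, g))  # 7: centre + 6 faces
#' @export
buildSphere <- function(centerMm, radiusMm, grid) {
  stopifnot(radiusMm > 0)
  out <- array(FALSE, gridDim(grid))
  # candidate voxel box around the centre, then exact distance test
  ctrVox <- solve(grid@affine, c(centerMm, 1))[1:3]
  vs <- voxelSizes(grid)
  lo <- pmax(floor(ctrVox - radiusMm / vs - 1), 0)
  hi <- pmin(ceiling(ctrVox + radiusMm / vs + 1), grid@dim - 1)
  if (any(lo > hi)) {
    warning("sphere lies entirely outside the grid", call. = FALSE)
    return(out)
  }
  idx <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                               z = lo[3]:hi[3]))
  mm <- rbind(voxelToMm(idx, grid))
  d2 <- (mm[, 1] - centerMm[1])^2 + (mm[, 2] - centerMm[2])^2 +
        (mm[, 3] - centerMm[3])^2
  hit <- idx[d2 <= radiusMm^2 + 1e-9, , drop = FALSE]
  if (nrow(hit) == 0L) {
    warning("sphere contains no voxel centre", call. = FALSE)
    return(out)
  }
  out[voxelIndex(hit, grid)] <- TRUE
  out
}

#' Build a contrast's merged-sphere seed mask
#'
#' Places a sphere of `radiusMm` at every peak of the contrast, takes the
#' voxelwise union, and intersects with the brain mask so seed time
#' series never average non-brain voxels. Duplicate peaks are harmless
#' (the union is idempotent). Every peak always contributes at least the
#' voxel that contains it: with a radius smaller than the voxel spacing
#' (e.g. a 1 mm sphere on a 3 mm lattice) the closed ball around an
#' off-centre coordinate may hold no voxel centre at all, and the peak
#' would otherwise vanish from its own seed.
#'
#' @param contrast a [StudyContrast-class] with at least one in-mask
#'   peak, coordinates in MNI mm.
#' @param radiusMm sphere radius in mm (default 4; 1 and 7 are the usual
#'   sensitivity settings).
#' @param grid analysis [VolumeGrid-class].
#' @param mask [BrainMask-class] to intersect with.
#' @return A [SeedMask-class].
#' @export
buildSeedMask <- function(contrast, radiusMm = 4, grid, mask) {
  stopifnotSameGrid(grid, mask, "seed grid and brain mask")
  xyz <- as.matrix(contrast@peaks[, c("x", "y", "z")])
  un <- array(FALSE, gridDim(grid))
  for (i in seq_len(nrow(xyz))) {
    sph <- suppressWarnings(buildSphere(xyz[i, ], radiusMm, grid))
    nv <- mmToVoxel(xyz[i, ], grid)            # containing voxel fallback
    if (all(nv >= 0) && all(nv <= grid@dim - 1L))
      sph[voxelIndex(nv, grid)] <- TRUE
    un <- un | sph
  }
  un <- un & maskValues(mask)
  if (!any(un))
    stop("seed mask for contrast '", contrast@contrastId,
         "' is empty after masking", call. = FALSE)
  new("SeedMask", contrastId = contrast@contrastId, grid = theGrid(grid),
      values = un, radiusMm = radiusMm)
}

#' Build seed masks for a set of contrasts
#'
#' @param contrasts named list of [StudyContrast-class] objects.
#' @inheritParams buildSeedMask
#' @return Named list of [SeedMask-class] objects.
#' @export
buildSeedMasks <- function(contrasts, radiusMm = 4, grid, mask) {
  out <- lapply(contrasts, buildSeedMask, radiusMm = radiusMm,
                grid = grid, mask = mask)
  names(out) <- vapply(out, contrastId, character(1))
  out
}
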