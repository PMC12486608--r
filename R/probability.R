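#' Merge binarised contrast maps into a network probability map
#'
#' Each voxel's value is the fraction of contrasts whose thresholded
#' group network map contains it — exact counts over `n` contrasts, so
#' values are multiples of `1/n`.
#'
#' @param maps list of [GroupNetworkMap-class] objects on one grid (or
#'   list of logical arrays plus `grid`).
#' @param grid required when raw arrays are given.
#' @return A [ProbabilityMap-class].
#' @export
probabilityMap <- function(maps, grid = NULL) {
  if (!length(maps)) stop("need at least one binarised map")
  if (is(maps[[1]], "GroupNetworkMap")) {
    grid <- maps[[1]]@grid
    for (m in maps) stopifnotSameGrid(maps[[1]], m, "group maps")
    bins <- lapply(maps, function(m) m@binary)
  } else {
    if (is.null(grid)) stop("grid is required for raw arrays")
    bins <- maps
  }
  counts <- Reduce(`+`, lapply(bins, function(b) array(as.numeric(b),
                                                       gridDim(grid))))
  new("ProbabilityMap", grid = theGrid(grid),
      values = counts / length(bins), nContrasts = length(bins))
}

#' Threshold a probability map into the convergent network mask
#'
#' The default keeps voxels present in strictly more than `tau` of the
#' contrasts (a voxel connected to more than 50% of the contrast seeds),
#' i.e. `value > tau`; set `inclusive = TRUE` for `value >= tau`.
#'
#' @param prob a [ProbabilityMap-class].
#' @param tau threshold in (0, 1] (default 0.5).
#' @param inclusive use `>=` instead of the strict `>`.
#' @return A logical array on the probability map's grid.
#' @export
thresholdProbability <- function(prob, tau = 0.5, inclusive = FALSE) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  if (inclusive) prob@values >= tau - 1e-12 else prob@values > tau + 1e-12
}

#' Overlap of a network mask with each canonical network
#'
#' For every atlas network k the ratio
#' `|mask & atlas_k & brain| / |atlas_k & brain|` is computed; networks
#' reaching at least `sigThreshold` (default 10%) are flagged
#' significant. Denominators are restricted to the analysis brain mask
#' so atlas voxels with no data cannot dilute the ratio.
#'
#' @param networkMask logical array (e.g. from
#'   [thresholdProbability()]).
#' @param atlas a [CanonicalAtlas-class] on the same grid.
#' @param brain analysis [BrainMask-class].
#' @param sigThreshold significance cut-off on the ratio (default 0.10).
#' @return data.frame: `network`, `canonical_voxels`, `overlap_voxels`,
#'   `ratio`, `significant`, ordered by atlas label.
#' @export
overlapRatios <- function(networkMask, atlas, brain,
                          sigThreshold = 0.10) {
  stopifnotSameGrid(atlas, brain, "atlas and brain mask")
  if (!identical(dim(networkMask), gridDim(atlas)))
    stop("network mask dimensions do not match the atlas grid")
  labs <- atlas@labels
  bm <- maskValues(brain)
  out <- data.frame(network = character(), canonical_voxels = integer(),
                    overlap_voxels = integer(), ratio = numeric(),
                    significant = logical(), stringsAsFactors = FALSE)
  for (k in seq_along(atlas@networkNames)) {
    canon <- labs == k & bm
    nCanon <- sum(canon)
    if (nCanon == 0L)
      stop("canonical network '", atlas@networkNames[k],
           "' is empty within the brain mask")
    nOver <- sum(canon & networkMask)
    ratio <- nOver / nCanon
    out <- rbind(out, data.frame(
      network = atlas@networkNames[k], canonical_voxels = nCanon,
      overlap_voxels = nOver, ratio = ratio,
      significant = ratio >= sigThreshold, stringsAsFactors = FALSE))
  }
  out
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays of identical dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
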