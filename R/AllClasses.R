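#' @import methods
NULL

#' Sampling grid of a brain volume
#'
#' A `VolumeGrid` defines the discrete sampling lattice every volume in an
#' analysis lives on: the array dimensions and the 4x4 affine mapping 0-based
#' voxel indices to world (RAS mm) coordinates. All volumes entering a single
#' pipeline run must share one grid; operations check this and fail loudly on
#' mismatch rather than resampling silently.
#'
#' @slot dim integer(3), positive array dimensions.
#' @slot affine 4x4 numeric matrix, voxel-index (0-based) to mm transform;
#'   must be invertible with positive voxel volume.
#'
#' @seealso [volumeGrid()], [mmToVoxel()], [voxelToMm()]
#' @export
setClass("VolumeGrid",
  representation(dim = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dim) != 3L || any(object@dim < 1L))
      msg <- c(msg, "dim must be three positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else {
      d <- det(object@affine[1:3, 1:3, drop = FALSE])
      if (!is.finite(d) || abs(d) < .Machine$double.eps)
        msg <- c(msg, "affine must be invertible")
      if (!all(object@affine[4, ] == c(0, 0, 0, 1)))
        msg <- c(msg, "last affine row must be (0, 0, 0, 1)")
    }
    if (length(msg)) msg else TRUE
  })

#' Boolean brain (or gray-matter) mask on a grid
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values logical array with `dim(grid)` dimensions; at least one
#'   voxel must be `TRUE`.
#'
#' @seealso [brainMask()], [screenPeaks()]
#' @export
setClass("BrainMask",
  representation(grid = "VolumeGrid", values = "array"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@values))
      msg <- c(msg, "values must be a logical array")
    if (!identical(dim(object@values), object@grid@dim))
      msg <- c(msg, "values dimensions must match the grid")
    if (!any(object@values))
      msg <- c(msg, "mask must contain at least one TRUE voxel")
    if (length(msg)) msg else TRUE
  })

#' Merged-sphere seed mask for one contrast
#'
#' Union of spheres centred on a contrast's peak coordinates, intersected
#' with the brain mask used at construction time.
#'
#' @slot contrastId character scalar identifying the originating contrast.
#' @slot grid a [VolumeGrid-class].
#' @slot values logical array, non-empty.
#' @slot radiusMm positive sphere radius in mm.
#'
#' @seealso [buildSeedMask()], [buildSphere()]
#' @export
setClass("SeedMask",
  representation(contrastId = "character", grid = "VolumeGrid",
                 values = "array", radiusMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@values) ||
        !identical(dim(object@values), object@grid@dim))
      msg <- c(msg, "values must be a logical array on the grid")
    if (!any(object@values))
      msg <- c(msg, "seed mask must be non-empty")
    if (length(object@radiusMm) != 1L || object@radiusMm <= 0)
      msg <- c(msg, "radiusMm must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' 4-D BOLD time series on a grid
#'
#' Voxel time series are stored as a voxels-by-time matrix in grid
#' column-major voxel order; [boldArray()] reconstructs the 4-D array view.
#' This layout keeps the whole preprocessing chain (confound regression,
#' filtering, correlation) in dense matrix algebra.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values numeric matrix, `prod(dim(grid))` rows by `nVolumes` columns.
#' @slot trSeconds positive repetition time in seconds.
#'
#' @seealso [bold4D()], [preprocessBold()], [fcMap()]
#' @export
setClass("Bold4D",
  representation(grid = "VolumeGrid", values = "matrix",
                 trSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != prod(object@grid@dim))
      msg <- c(msg, "values must have one row per grid voxel")
    if (ncol(object@values) < 2L)
      msg <- c(msg, "at least 2 volumes are required")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' One study contrast with its peak list and subgroup metadata
#'
#' A contrast is one reported group comparison (for example, a gray-matter
#' decrease in patients relative to controls) contributing a set of peak
#' coordinates. Peaks are kept in reported order; the `space` column records
#' whether they are MNI or Talairach until harmonisation.
#'
#' @slot studyId character scalar.
#' @slot contrastId character scalar, unique within a run.
#' @slot peaks data.frame with columns `x`, `y`, `z` (mm) and `space`
#'   (`"MNI"` or `"Talairach"`).
#' @slot direction `"GM_decrease"` or `"GM_increase"`.
#' @slot sexFemaleOnly logical scalar, `NA` when unknown.
#' @slot ageGroup `"adolescent"`, `"adult"`, `"mixed"` or `"unknown"`.
#' @slot clinicalState free-text clinical state.
#'
#' @seealso [readContrastTable()], [contrastToMni()], [selectContrasts()]
#' @export
setClass("StudyContrast",
  representation(studyId = "character", contrastId = "character",
                 peaks = "data.frame", direction = "character",
                 sexFemaleOnly = "logical", ageGroup = "character",
                 clinicalState = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("x", "y", "z", "space")
    if (!all(need %in% names(object@peaks)))
      msg <- c(msg, "peaks must have columns x, y, z, space")
    else {
      xyz <- as.matrix(object@peaks[, c("x", "y", "z")])
      if (nrow(xyz) < 1L)
        msg <- c(msg, "a contrast needs at least one peak")
      if (!all(is.finite(xyz)))
        msg <- c(msg, "peak coordinates must be finite")
      if (!all(object@peaks$space %in% c("MNI", "Talairach")))
        msg <- c(msg, "space must be 'MNI' or 'Talairach'")
    }
    if (!object@direction %in% c("GM_decrease", "GM_increase"))
      msg <- c(msg, "direction must be GM_decrease or GM_increase")
    if (!object@ageGroup %in% c("adolescent", "adult", "mixed", "unknown"))
      msg <- c(msg, "ageGroup must be adolescent/adult/mixed/unknown")
    if (length(msg)) msg else TRUE
  })

#' Group-level thresholded network map for one contrast
#'
#' Result of the voxelwise one-sample t-test on a stack of subject
#' Fisher-Z maps, with Benjamini-Hochberg FDR control and restriction to
#' positive connectivity.
#'
#' @slot contrastId character scalar.
#' @slot grid a [VolumeGrid-class].
#' @slot tValues numeric array of t statistics (0 outside the mask).
#' @slot dof degrees of freedom (subjects - 1).
#' @slot pValues numeric array of one-sided p values (1 outside the mask).
#' @slot binary logical array: in-mask, FDR-rejected, positive-t voxels.
#' @slot qLevel FDR level used.
#' @slot pThreshold realised Benjamini-Hochberg p cut-off (`NA` when the
#'   rejection set is empty).
#'
#' @seealso [groupNetworkMap()], [probabilityMap()]
#' @export
setClass("GroupNetworkMap",
  representation(contrastId = "character", grid = "VolumeGrid",
                 tValues = "array", dof = "numeric", pValues = "array",
                 binary = "array", qLevel = "numeric",
                 pThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- object@grid@dim
    for (nm in c("tValues", "pValues", "binary"))
      if (!identical(dim(slot(object, nm)), d))
        msg <- c(msg, sprintf("%s dimensions must match the grid", nm))
    if (!is.logical(object@binary))
      msg <- c(msg, "binary must be logical")
    if (object@qLevel <= 0 || object@qLevel >= 1)
      msg <- c(msg, "qLevel must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Across-contrast network probability map
#'
#' Voxelwise fraction of contrasts whose binarised group map contains the
#' voxel. Values are exact multiples of `1 / nContrasts`.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot values numeric array of fractions in `[0, 1]`.
#' @slot nContrasts number of contrast maps merged.
#'
#' @seealso [probabilityMap()], [thresholdProbability()]
#' @export
setClass("ProbabilityMap",
  representation(grid = "VolumeGrid", values = "array",
                 nContrasts = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), object@grid@dim))
      msg <- c(msg, "values dimensions must match the grid")
    if (object@nContrasts < 1L)
      msg <- c(msg, "nContrasts must be positive")
    counts <- object@values * object@nContrasts
    if (any(abs(counts - round(counts)) > 1e-9) ||
        any(object@values < 0) || any(object@values > 1))
      msg <- c(msg, "values must be k/nContrasts fractions in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Canonical-network atlas as an integer label volume
#'
#' @slot grid a [VolumeGrid-class].
#' @slot labels integer array; 0 is background, positive labels index
#'   `networkNames`.
#' @slot networkNames character vector naming labels `1..K`.
#'
#' @seealso [overlapRatios()], [makeAtlas()]
#' @export
setClass("CanonicalAtlas",
  representation(grid = "VolumeGrid", labels = "array",
                 networkNames = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@labels), object@grid@dim))
      msg <- c(msg, "labels dimensions must match the grid")
    labs <- unique(as.integer(object@labels))
    labs <- labs[labs > 0L]
    if (length(labs) && max(labs) > length(object@networkNames))
      msg <- c(msg, "every nonzero label must have a network name")
    if (anyNA(object@networkNames) || any(object@networkNames == ""))
      msg <- c(msg, "network names must be non-empty")
    if (length(msg)) msg else TRUE
  })
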