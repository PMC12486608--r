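#' Construct a BrainMask
#'
#' @param values logical (or coercible) array on `grid`.
#' @param grid a [VolumeGrid-class].
#' @return A [BrainMask-class].
#' @export
brainMask <- function(values, grid) {
  v <- array(as.logical(values), dim = gridDim(grid))
  new("BrainMask", grid = theGrid(grid), values = v)
}

#' Construct a Bold4D from a 4-D array or voxels-by-time matrix
#'
#' @param values 4-D numeric array (`x, y, z, t`) or a matrix with
#'   `prod(dim(grid))` rows and one column per volume.
#' @param grid a [VolumeGrid-class].
#' @param trSeconds repetition time in seconds.
#' @return A [Bold4D-class].
#' @export
bold4D <- function(values, grid, trSeconds) {
  if (is.array(values) && length(dim(values)) == 4L) {
    stopifnot(identical(dim(values)[1:3], as.integer(gridDim(grid))))
    values <- matrix(values, nrow = prod(dim(values)[1:3]))
  }
  new("Bold4D", grid = theGrid(grid), values = values,
      trSeconds = as.numeric(trSeconds))
}

#' Value accessors for volume-like objects
#'
#' `maskValues()` returns the logical array of a mask or seed;
#' `probValues()` the fraction array of a [ProbabilityMap-class];
#' `atlasLabels()` and `networkNames()` the label volume and names of a
#' [CanonicalAtlas-class]; `boldMatrix()` the voxels-by-time matrix and
#' `boldArray()` the 4-D array view of a [Bold4D-class]; `nVolumes()` and
#' `repetitionTime()` its time axis; `tValues()`, `pValues()` and
#' `binaryMap()` the components of a [GroupNetworkMap-class];
#' `contrastId()` the contrast identifier of seeds and group maps.
#'
#' @param x the object.
#' @name value-accessors
NULL

#' @rdname value-accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
setMethod("maskValues", "BrainMask", function(x) x@values)
setMethod("maskValues", "SeedMask", function(x) x@values)

#' @rdname value-accessors
#' @export
probValues <- function(x) x@values

#' @rdname value-accessors
#' @export
atlasLabels <- function(x) x@labels

#' @rdname value-accessors
#' @export
networkNames <- function(x) x@networkNames

#' @rdname value-accessors
#' @export
boldMatrix <- function(x) x@values

#' @rdname value-accessors
#' @export
boldArray <- function(x) array(x@values, dim = c(gridDim(x), ncol(x@values)))

#' @rdname value-accessors
#' @export
nVolumes <- function(x) ncol(x@values)

#' @rdname value-accessors
#' @export
repetitionTime <- function(x) x@trSeconds

#' @rdname value-accessors
#' @export
setGeneric("contrastId", function(x) standardGeneric("contrastId"))
setMethod("contrastId", "StudyContrast", function(x) x@contrastId)
setMethod("contrastId", "SeedMask", function(x) x@contrastId)
setMethod("contrastId", "GroupNetworkMap", function(x) x@contrastId)

#' @rdname value-accessors
#' @export
tValues <- function(x) x@tValues

#' @rdname value-accessors
#' @export
pValues <- function(x) x@pValues

#' @rdname value-accessors
#' @export
binaryMap <- function(x) x@binary

#' @rdname value-accessors
#' @export
peakTable <- function(x) x@peaks

#' @rdname value-accessors
#' @export
seedRadius <- function(x) x@radiusMm

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask: %d of %d voxels in mask\n",
              sum(object@values), nVoxels(object)))
  show(object@grid)
})

setMethod("show", "SeedMask", function(object) {
  cat(sprintf("SeedMask '%s': %d voxels, radius %g mm\n",
              object@contrastId, sum(object@values), object@radiusMm))
})

setMethod("show", "Bold4D", function(object) {
  cat(sprintf("Bold4D: %s grid, %d volumes, TR %g s\n",
              paste(gridDim(object), collapse = "x"),
              nVolumes(object), object@trSeconds))
})

setMethod("show", "StudyContrast", function(object) {
  cat(sprintf(
    "StudyContrast '%s' (study %s): %d peak(s), %s, female-only=%s, age=%s\n",
    object@contrastId, object@studyId, nrow(object@peaks),
    object@direction, object@sexFemaleOnly, object@ageGroup))
})

setMethod("show", "GroupNetworkMap", function(object) {
  cat(sprintf(
    "GroupNetworkMap '%s': dof %d, q %.3g, %d suprathreshold voxel(s)\n",
    object@contrastId, as.integer(object@dof), object@qLevel,
    sum(object@binary)))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap over %d contrasts; %d voxel(s) > 0\n",
              object@nContrasts, sum(object@values > 0)))
})

setMethod("show", "CanonicalAtlas", function(object) {
  cat(sprintf("CanonicalAtlas: %d network(s): %s\n",
              length(object@networkNames),
              paste(object@networkNames, collapse = ", ")))
})
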