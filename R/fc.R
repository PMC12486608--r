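#' Extract a seed's mean time series
#'
#' @param bold a [Bold4D-class].
#' @param seed a [SeedMask-class] on the same grid.
#' @return Numeric vector (one mean per volume) with attribute
#'   `zeroVariance` set to `TRUE` when the series is constant — the FC
#'   map of such a seed is all zero, with a warning.
#' @export
seedTimeSeries <- function(bold, seed) {
  stopifnotSameGrid(bold, seed, "BOLD and seed")
  idx <- which(as.vector(maskValues(seed)))
  if (!length(idx)) stop("seed mask is empty")
  s <- colMeans(bold@values[idx, , drop = FALSE])
  zv <- stats::sd(s) == 0
  if (zv)
    warning("seed '", seed@contrastId, "' has a zero-variance time series",
            call. = FALSE)
  attr(s, "zeroVariance") <- zv
  s
}

#' Seed-to-whole-brain Fisher-Z connectivity map
#'
#' Pearson correlation of the seed series with every in-mask voxel's
#' series, Fisher-Z transformed (`z = atanh(r)`). `r` is clipped to
#' `1 - 1e-7` in magnitude before the transform so perfectly (anti-)
#' correlated voxels map to finite z of about +/- 8.0. Zero-variance
#' voxels (and all voxels, when the seed itself is flat) get z = 0; their
#' count is recorded in the `zeroVariance` attribute. Out-of-mask voxels
#' are 0.
#'
#' @param bold a preprocessed [Bold4D-class].
#' @param seedSeries numeric vector from [seedTimeSeries()] (length =
#'   volumes).
#' @param mask analysis [BrainMask-class].
#' @param contrastId,subjectId identifiers stored in the result's
#'   dimnames-free attributes.
#' @return 3-D numeric array of Fisher-Z values with attributes
#'   `contrastId`, `subjectId`, `zeroVariance`.
#' @export
fcMap <- function(bold, seedSeries, mask, contrastId = "",
                  subjectId = "") {
  stopifnotSameGrid(bold, mask, "BOLD and mask")
  s <- as.numeric(seedSeries)
  if (length(s) != nVolumes(bold))
    stop("seed series length (", length(s),
         ") does not match BOLD volumes (", nVolumes(bold), ")")
  idx <- which(as.vector(maskValues(mask)))
  z <- numeric(nVoxels(bold))
  nZero <- 0L
  sc <- s - mean(s)
  sNorm <- sqrt(sum(sc^2))
  if (sNorm == 0) {
    warning("seed series has zero variance; FC map set to 0",
            call. = FALSE)
    nZero <- length(idx)
  } else {
    Y <- bold@values[idx, , drop = FALSE]
    Yc <- Y - rowMeans(Y)
    yNorm <- sqrt(rowSums(Yc^2))
    r <- as.vector(Yc %*% sc) / (yNorm * sNorm)
    zero <- yNorm == 0
    r[zero] <- 0
    nZero <- sum(zero)
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z[idx] <- atanh(r)
    z[idx][zero] <- 0
  }
  out <- array(z, gridDim(bold))
  attr(out, "contrastId") <- contrastId
  attr(out, "subjectId") <- subjectId
  attr(out, "zeroVariance") <- nZero
  out
}
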