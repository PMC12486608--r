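#' Framewise displacement (Power formulation)
#'
#' FD(t) = sum of absolute backward differences of the three translations
#' (mm) plus the three rotations (radians) converted to arc length on a
#' 50 mm sphere. The first volume has FD 0 by convention.
#'
#' @param motion n-by-6 motion matrix: translations (mm) then rotations
#'   (radians); see [readMotionFile()].
#' @param headRadiusMm sphere radius for the rotation-to-mm conversion.
#' @return Numeric vector of per-volume FD in mm.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.5
#' computeFD(m)  # 0 0 0.5 0.5 0
#' @export
computeFD <- function(motion, headRadiusMm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("need at least 2 volumes to compute FD")
  if (ncol(motion) != 6L) stop("motion matrix must have 6 columns")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
        headRadiusMm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Check gross head-motion exclusion limits
#'
#' A subject fails when any absolute translation reaches `maxTransMm` or
#' any absolute rotation reaches `maxRotDeg`; failing subjects are
#' excluded from group stacking.
#'
#' @inheritParams computeFD
#' @param maxTransMm translation limit in mm (default 2).
#' @param maxRotDeg rotation limit in degrees (default 2).
#' @return List with `pass` (logical), `maxTranslationMm`,
#'   `maxRotationDeg`, and `failingVolumes` (1-based indices).
#' @export
checkMotionLimits <- function(motion, maxTransMm = 2, maxRotDeg = 2) {
  motion <- as.matrix(motion)
  trans <- abs(motion[, 1:3, drop = FALSE])
  rotDeg <- abs(motion[, 4:6, drop = FALSE]) * 180 / pi
  bad <- apply(trans, 1L, max) >= maxTransMm |
         apply(rotDeg, 1L, max) >= maxRotDeg
  list(pass = !any(bad),
       maxTranslationMm = max(trans),
       maxRotationDeg = max(rotDeg),
       failingVolumes = which(bad))
}

#' Friston 24-parameter motion expansion
#'
#' Columns are the 6 rigid-body parameters, their one-volume backward
#' differences (first row zero), and the squares of both sets: 24 columns
#' in all.
#'
#' @inheritParams computeFD
#' @return n-by-24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  if (ncol(motion) != 6L) stop("motion matrix must have 6 columns")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0("d_", base), paste0(base, "_sq"),
                     paste0("d_", base, "_sq"))
  out
}

#' Spike (scrubbing) regressors from framewise displacement
#'
#' One indicator column per volume whose FD strictly exceeds the
#' threshold; each column is 1 at that volume and 0 elsewhere. Volumes at
#' exactly the threshold are not spikes.
#'
#' @param fd per-volume FD vector from [computeFD()].
#' @param thresholdMm spike threshold in mm (default 0.5).
#' @return n-by-k indicator matrix (k = number of spike volumes; 0
#'   columns when none).
#' @export
spikeRegressors <- function(fd, thresholdMm = 0.5) {
  spikes <- which(fd > thresholdMm)
  out <- matrix(0, nrow = length(fd), ncol = length(spikes))
  for (j in seq_along(spikes)) out[spikes[j], j] <- 1
  if (length(spikes))
    colnames(out) <- paste0("spike_", spikes)
  out
}

#' Mean time series over a mask
#'
#' @param bold a [Bold4D-class].
#' @param mask a [BrainMask-class] on the same grid.
#' @return Numeric vector, one arithmetic mean per volume.
#' @export
tissueMeanSeries <- function(bold, mask) {
  stopifnotSameGrid(bold, mask, "BOLD and mask")
  idx <- which(as.vector(maskValues(mask)))
  if (!length(idx)) stop("mask is empty")
  colMeans(bold@values[idx, , drop = FALSE])
}

#' Assemble the nuisance design matrix
#'
#' Builds the per-volume confound design: intercept, linear drift, the
#' Friston-24 motion expansion, spike indicators for FD > `fdThresholdMm`
#' volumes, and mean signals over the supplied tissue masks (global /
#' white matter / cerebrospinal fluid; any subset may be given).
#'
#' @param motion n-by-6 motion matrix (translations mm, rotations rad).
#' @param bold a [Bold4D-class] (needed for tissue means; may be omitted
#'   when no tissue masks are supplied).
#' @param globalMask,wmMask,csfMask optional [BrainMask-class] objects
#'   whose mean series are added as regressors.
#' @param fdThresholdMm spike threshold in mm (default 0.5).
#' @return Numeric matrix with named columns, `nrow` = volumes.
#' @export
confoundDesign <- function(motion, bold = NULL, globalMask = NULL,
                           wmMask = NULL, csfMask = NULL,
                           fdThresholdMm = 0.5) {
  motion <- as.matrix(motion)
  n <- nrow(motion)
  if (!is.null(bold) && nVolumes(bold) != n)
    stop("motion rows (", n, ") do not match BOLD volumes (",
         nVolumes(bold), ")")
  drift <- seq_len(n) - (n + 1) / 2          # centred linear trend
  X <- cbind(intercept = 1, drift = drift, friston24(motion))
  fd <- computeFD(motion)
  X <- cbind(X, spikeRegressors(fd, fdThresholdMm))
  addTissue <- function(X, mask, nm) {
    if (is.null(mask)) return(X)
    if (is.null(bold)) stop("bold is required for tissue regressors")
    s <- tissueMeanSeries(bold, mask)
    cbind(X, structure(matrix(s, ncol = 1),
                       dimnames = list(NULL, nm)))
  }
  X <- addTissue(X, globalMask, "global")
  X <- addTissue(X, wmMask, "white_matter")
  X <- addTissue(X, csfMask, "csf")
  X
}

#' Regress confounds out of a BOLD series
#'
#' Voxelwise ordinary-least-squares residualisation against the design.
#' Exactly duplicated columns are dropped (keeping the first of each
#' group); a design that remains rank-deficient raises an error listing
#' the collinear columns. The intercept guarantees (numerically)
#' zero-mean residuals.
#'
#' @param bold a [Bold4D-class].
#' @param design confound matrix from [confoundDesign()] (rows =
#'   volumes). An intercept column is added if absent.
#' @return A [Bold4D-class] of residuals.
#' @export
regressConfounds <- function(bold, design) {
  X <- as.matrix(design)
  if (nrow(X) != nVolumes(bold))
    stop("design rows (", nrow(X), ") do not match BOLD volumes (",
         nVolumes(bold), ")")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("c", seq_len(ncol(X)))
  if (!any(apply(X, 2L, function(v) all(v == v[1]) && v[1] != 0)))
    X <- cbind(intercept = 1, X)
  dup <- duplicated(t(X))
  if (any(dup)) X <- X[, !dup, drop = FALSE]
  allZero <- colSums(X != 0) == 0L            # e.g. motionless derivatives
  if (any(allZero)) X <- X[, !allZero, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- t(bold@values)                         # time x voxels
  resid <- qr.resid(qrX, Y)
  initialize(bold, values = t(resid))
}
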