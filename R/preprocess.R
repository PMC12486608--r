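# squared-magnitude response of a digital filter at radian frequencies w
filterGain2 <- function(b, a, w) {
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)),
                complex(1))
  Mod(num / den)^2
}

#' Zero-phase band-pass filter a BOLD series
#'
#' Designs a 4th-order Butterworth band-pass for the series' sampling
#' rate and applies its zero-phase (squared-magnitude, as in
#' forward-backward filtering) response in the frequency domain to every
#' voxel at once. The DC component is removed entirely; mid-band
#' components pass essentially unattenuated.
#'
#' @param bold a [Bold4D-class].
#' @param lowHz,highHz band edges in Hz (defaults 0.01 and 0.1, the
#'   standard resting-state band). `highHz` must be below the Nyquist
#'   frequency `1 / (2 TR)`.
#' @param order Butterworth order (default 4).
#' @return Filtered [Bold4D-class].
#' @export
bandpassBold <- function(bold, lowHz = 0.01, highHz = 0.1, order = 4) {
  fs <- 1 / bold@trSeconds
  nyq <- fs / 2
  if (highHz >= nyq)
    stop(sprintf("highHz (%g) must be below Nyquist (%g Hz)", highHz, nyq))
  if (lowHz <= 0 || lowHz >= highHz)
    stop("need 0 < lowHz < highHz")
  filt <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  n <- nVolumes(bold)
  w <- 2 * pi * (seq_len(n) - 1) / n
  gain <- filterGain2(filt$b, filt$a, w)
  Y <- t(bold@values)                      # time x voxels
  Yf <- Re(stats::mvfft(stats::mvfft(Y) * gain, inverse = TRUE)) / n
  initialize(bold, values = t(Yf))
}

# per-axis Gaussian kernel matrix (zero-padded convolution)
gaussKernelMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok]
  }
  K
}

smoothArray3D <- function(arr, kernels) {
  d <- dim(arr)
  m <- kernels[[1]] %*% matrix(arr, d[1], d[2] * d[3])
  arr <- array(m, d)
  arr <- aperm(arr, c(2, 1, 3))
  m <- kernels[[2]] %*% matrix(arr, d[2], d[1] * d[3])
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  m <- matrix(arr, d[1] * d[2], d[3]) %*% t(kernels[[3]])
  array(m, d)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2))
#' per axis (in mm, converted to voxels from the grid affine), applied
#' volume by volume with zero padding at the grid boundary. `fwhmMm = 0`
#' is the identity.
#'
#' @param x a [Bold4D-class] or a 3-D numeric array.
#' @param fwhmMm full width at half maximum in mm (default 6; scalar or
#'   per-axis length 3).
#' @param grid required when `x` is a raw array.
#' @return Object of the same kind as `x`.
#' @export
smoothVolume <- function(x, fwhmMm = 6, grid = NULL) {
  if (any(fwhmMm < 0)) stop("fwhmMm must be non-negative")
  fwhm <- rep(fwhmMm, length.out = 3)
  if (is(x, "Bold4D")) grid <- x@grid
  if (is.null(grid)) stop("grid is required for array input")
  if (all(fwhm == 0)) return(x)
  sigmaVox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxelSizes(grid)
  d <- gridDim(grid)
  kernels <- lapply(1:3, function(ax) gaussKernelMatrix(d[ax],
                                                        sigmaVox[ax]))
  if (is(x, "Bold4D")) {
    vals <- x@values
    for (t in seq_len(ncol(vals)))
      vals[, t] <- as.vector(smoothArray3D(array(vals[, t], d), kernels))
    return(initialize(x, values = vals))
  }
  smoothArray3D(x, kernels)
}

#' Run the full confound-removal stage on one subject
#'
#' Applies, in order: nuisance regression (linear drift, Friston-24,
#' FD-based spike regressors, optional global / white-matter / CSF mean
#' signals), zero-phase band-pass filtering, and Gaussian smoothing.
#' Inputs are assumed motion-corrected and co-registered to the analysis
#' grid; the stage is deterministic.
#'
#' @param bold a [Bold4D-class].
#' @param motion n-by-6 motion matrix (translations mm, rotations
#'   radians).
#' @param globalMask,wmMask,csfMask optional [BrainMask-class] tissue
#'   masks for mean-signal regressors.
#' @param fdThresholdMm spike threshold (default 0.5 mm).
#' @param lowHz,highHz band-pass edges (defaults 0.01-0.1 Hz).
#' @param fwhmMm smoothing kernel FWHM (default 6 mm).
#' @return Preprocessed [Bold4D-class].
#' @export
preprocessBold <- function(bold, motion, globalMask = NULL, wmMask = NULL,
                           csfMask = NULL, fdThresholdMm = 0.5,
                           lowHz = 0.01, highHz = 0.1, fwhmMm = 6) {
  X <- confoundDesign(motion, bold, globalMask = globalMask,
                      wmMask = wmMask, csfMask = csfMask,
                      fdThresholdMm = fdThresholdMm)
  out <- regressConfounds(bold, X)
  out <- bandpassBold(out, lowHz = lowHz, highHz = highHz)
  smoothVolume(out, fwhmMm = fwhmMm)
}
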