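#' Voxelwise one-sample t-test over a subject stack
#'
#' For each in-mask voxel, tests whether the mean Fisher-Z connectivity
#' across subjects exceeds zero: `t = mean / (sd / sqrt(n))` with
#' `n - 1` degrees of freedom. The default alternative is one-sided
#' positive (`"greater"`), matching an analysis that considers positive
#' connectivity only; `"two.sided"` is available for the variant that
#' tests both tails and masks to positive t afterwards.
#'
#' Degenerate voxels: zero spread with positive mean gives p = 0 (t is
#' reported as `Inf`); zero spread with zero mean gives t = 0 and
#' p = 0.5 (one-sided) or 1 (two-sided).
#'
#' @param zStack voxels-by-subjects matrix, or a list of 3-D z-map
#'   arrays from [fcMap()] on one grid.
#' @param mask analysis [BrainMask-class] (or `NULL` to test every row).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `t` and `p` vectors over all voxels (0 / 1 outside
#'   the mask respectively), `dof`, and `maskIndex` (in-mask linear
#'   indices).
#' @export
oneSampleT <- function(zStack, mask = NULL,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.list(zStack))
    zStack <- vapply(zStack, as.vector, numeric(length(zStack[[1]])))
  n <- ncol(zStack)
  if (n < 3L) stop("need at least 3 subjects for group inference")
  idx <- if (is.null(mask)) seq_len(nrow(zStack))
         else which(as.vector(maskValues(mask)))
  Y <- zStack[idx, , drop = FALSE]
  m <- rowMeans(Y)
  sdv <- sqrt(rowSums((Y - m)^2) / (n - 1))
  tv <- numeric(length(idx))
  pv <- numeric(length(idx))
  ok <- sdv > 0
  tv[ok] <- m[ok] / (sdv[ok] / sqrt(n))
  dof <- n - 1
  if (alternative == "greater") {
    pv[ok] <- stats::pt(tv[ok], dof, lower.tail = FALSE)
    pv[!ok] <- ifelse(m[!ok] > 0, 0, ifelse(m[!ok] < 0, 1, 0.5))
  } else {
    pv[ok] <- 2 * stats::pt(abs(tv[ok]), dof, lower.tail = FALSE)
    pv[!ok] <- ifelse(m[!ok] == 0, 1, 0)
  }
  tv[!ok] <- ifelse(m[!ok] > 0, Inf, ifelse(m[!ok] < 0, -Inf, 0))
  tAll <- numeric(nrow(zStack)); pAll <- rep(1, nrow(zStack))
  tAll[idx] <- tv; pAll[idx] <- pv
  list(t = tAll, p = pAll, dof = dof, maskIndex = idx)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with the p values sorted ascending, find the
#' largest k such that `p(k) <= k q / m`; reject every p value at or
#' below `p(k)`. When no such k exists the rejection set is empty and
#' the threshold is `NA`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `rejected` (logical, same length as `p`),
#'   `threshold` (the realised p cut-off, `NA` when nothing is
#'   rejected), and `nRejected`.
#' @examples
#' fdrBH(c(0.001, 0.5))$rejected   # TRUE FALSE
#' @export
fdrBH <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p values must lie in [0, 1] and be non-missing")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p)
  if (m < 1L) stop("need at least one p value")
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok))
    return(list(rejected = rep(FALSE, m), threshold = NA_real_,
                nRejected = 0L))
  thr <- ps[max(ok)]
  rejected <- p <= thr
  list(rejected = rejected, threshold = thr,
       nRejected = sum(rejected))
}

#' Threshold and binarise a group t map
#'
#' Combines the one-sample t-test with voxel-level FDR correction over
#' the in-mask family and restriction to positive connectivity:
#' a voxel enters the binary network map iff it is in the mask, in the
#' FDR rejection set, and has t > 0.
#'
#' @param zStack voxels-by-subjects matrix or list of z-map arrays.
#' @param mask analysis [BrainMask-class].
#' @param contrastId identifier for the resulting map.
#' @param q FDR level (default 0.05).
#' @param alternative passed to [oneSampleT()]; with `"two.sided"` the
#'   FDR family uses two-sided p values and the positive-t restriction
#'   does the masking.
#' @return A [GroupNetworkMap-class].
#' @export
groupNetworkMap <- function(zStack, mask, contrastId = "", q = 0.05,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tt <- oneSampleT(zStack, mask, alternative = alternative)
  bh <- fdrBH(tt$p[tt$maskIndex], q = q)
  rejected <- logical(length(tt$t))
  rejected[tt$maskIndex] <- bh$rejected
  binary <- rejected & tt$t > 0
  d <- gridDim(mask)
  new("GroupNetworkMap", contrastId = contrastId, grid = mask@grid,
      tValues = array(tt$t, d), dof = as.numeric(tt$dof),
      pValues = array(tt$p, d), binary = array(binary, d),
      qLevel = q, pThreshold = as.numeric(bh$threshold))
}
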