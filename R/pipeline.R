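#' Run the coordinate-to-network mapping pipeline in memory
#'
#' Executes the full analysis on already-loaded objects: peak-space
#' harmonisation, gray-matter screening, merged-sphere seed
#' construction, optional per-subject confound preprocessing, seed
#' connectivity mapping, group inference with voxel-level FDR,
#' probability-map thresholding, and (when an atlas is given) canonical
#' network overlap. Several radii can be requested at once; subject
#' preprocessing is shared across radii and contrasts, and per-radius
#' final masks are compared with Dice coefficients.
#'
#' @param contrasts named list of [StudyContrast-class] objects (any
#'   Talairach peaks are converted on entry).
#' @param subjects list of subjects, each a list with elements `bold`
#'   (a [Bold4D-class] or NIfTI path) and `motion` (n-by-6 matrix or
#'   motion-file path); alternatively a function `f(i)` returning such
#'   a list, with `nSubjects` giving the count.
#' @param brain analysis [BrainMask-class] (also the gray-matter screen
#'   and the FDR family).
#' @param atlas optional [CanonicalAtlas-class] for overlap ratios.
#' @param wm,csf optional tissue masks for the nuisance design.
#' @param nSubjects required when `subjects` is a function.
#' @param radiusMm seed radius (scalar, default 4) or vector of radii
#'   for a sensitivity run (e.g. `c(1, 4, 7)`).
#' @param q voxel-level FDR level (default 0.05).
#' @param tau probability-map threshold (default 0.5, strict `>`).
#' @param inclusiveTau use `>=` at the probability threshold.
#' @param alternative one-sample test sidedness (default `"greater"`).
#' @param sigThreshold overlap-significance cut-off (default 0.10).
#' @param fdThresholdMm,lowHz,highHz,fwhmMm preprocessing parameters
#'   (defaults 0.5 mm, 0.01-0.1 Hz, 6 mm).
#' @param globalSignal include the brain-mask mean regressor (default
#'   TRUE).
#' @param preprocess set to `FALSE` when the input series are already
#'   fully cleaned (regression, filtering and smoothing are skipped).
#' @param maxTransMm,maxRotDeg gross-motion exclusion limits.
#' @param trSeconds TR override for path-loaded BOLD files.
#' @param verbose emit per-stage progress messages.
#' @return List with `screening`, `includedSubjects`,
#'   `excludedSubjects`, `byRadius` (per radius: `seeds`, `groupMaps`,
#'   `probability`, `networkMask`, `overlap`), `diceTable` (data.frame
#'   of pairwise Dice between radii, `NULL` for a single radius), and
#'   `params`.
#' @export
runFCNM <- function(contrasts, subjects, brain, atlas = NULL,
                    wm = NULL, csf = NULL, nSubjects = NULL,
                    radiusMm = 4, q = 0.05, tau = 0.5,
                    inclusiveTau = FALSE,
                    alternative = c("greater", "two.sided"),
                    sigThreshold = 0.10, fdThresholdMm = 0.5,
                    lowHz = 0.01, highHz = 0.1, fwhmMm = 6,
                    globalSignal = TRUE, preprocess = TRUE,
                    maxTransMm = 2, maxRotDeg = 2, trSeconds = NULL,
                    verbose = TRUE) {
  alternative <- match.arg(alternative)
  if (any(radiusMm <= 0)) stop("radiusMm must be positive")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  say <- function(...) if (verbose) message(sprintf(...))

  getSubject <- if (is.function(subjects)) {
    if (is.null(nSubjects)) stop("nSubjects is required with a provider")
    subjects
  } else {
    nSubjects <- length(subjects)
    function(i) subjects[[i]]
  }

  # -- ingest: harmonise to MNI, screen against the gray-matter mask
  contrasts <- lapply(contrasts, peaksToMni)
  scr <- screenPeaks(contrasts, brain)
  if (!length(scr$contrasts))
    stop("no contrast survived gray-matter screening")
  say("ingest: %d contrast(s) kept, %d excluded",
      length(scr$contrasts), length(scr$excluded))

  # -- seeds, one set per radius
  seedSets <- lapply(radiusMm, function(r)
    buildSeedMasks(scr$contrasts, radiusMm = r, grid = brain@grid,
                   mask = brain))
  names(seedSets) <- as.character(radiusMm)
  nC <- length(scr$contrasts)

  # -- subject loop: preprocess once, map every seed of every radius
  zStacks <- lapply(radiusMm, function(r)
    vector("list", 0L))
  names(zStacks) <- as.character(radiusMm)
  included <- character(); excludedSubjects <- character()
  for (i in seq_len(nSubjects)) {
    subj <- getSubject(i)
    sid <- if (!is.null(subj$id)) subj$id else sprintf("sub-%02d", i)
    bold <- if (is.character(subj$bold))
      readBold(subj$bold, trSeconds = trSeconds) else subj$bold
    motion <- if (is.character(subj$motion))
      readMotionFile(subj$motion) else as.matrix(subj$motion)
    lim <- checkMotionLimits(motion, maxTransMm, maxRotDeg)
    if (!lim$pass) {
      warning(sprintf(
        "subject %s excluded: motion %.2f mm / %.2f deg exceeds limits",
        sid, lim$maxTranslationMm, lim$maxRotationDeg), call. = FALSE)
      excludedSubjects <- c(excludedSubjects, sid)
      next
    }
    if (preprocess)
      bold <- preprocessBold(bold, motion,
                             globalMask = if (globalSignal) brain,
                             wmMask = wm, csfMask = csf,
                             fdThresholdMm = fdThresholdMm,
                             lowHz = lowHz, highHz = highHz,
                             fwhmMm = fwhmMm)
    for (r in as.character(radiusMm)) {
      zmat <- matrix(0, nVoxels(brain), nC)
      for (j in seq_len(nC)) {
        sts <- seedTimeSeries(bold, seedSets[[r]][[j]])
        zmat[, j] <- as.vector(fcMap(bold, sts, brain))
      }
      zStacks[[r]][[length(zStacks[[r]]) + 1L]] <- zmat
    }
    included <- c(included, sid)
  }
  nS <- length(included)
  say("subjects: %d included, %d excluded", nS,
      length(excludedSubjects))
  if (nS < 3L) stop("fewer than 3 subjects passed motion screening")

  # -- group inference, probability map, overlap; per radius
  byRadius <- list()
  for (r in as.character(radiusMm)) {
    stack <- zStacks[[r]]
    groupMaps <- lapply(seq_len(nC), function(j) {
      zm <- vapply(stack, function(m) m[, j], numeric(nVoxels(brain)))
      groupNetworkMap(zm, brain,
                      contrastId = names(scr$contrasts)[j], q = q,
                      alternative = alternative)
    })
    names(groupMaps) <- names(scr$contrasts)
    prob <- probabilityMap(groupMaps)
    netMask <- thresholdProbability(prob, tau = tau,
                                    inclusive = inclusiveTau)
    overlap <- if (!is.null(atlas))
      overlapRatios(netMask, atlas, brain, sigThreshold = sigThreshold)
    say("radius %s mm: final mask has %d voxel(s)", r, sum(netMask))
    byRadius[[r]] <- list(radius = as.numeric(r), seeds = seedSets[[r]],
                          groupMaps = groupMaps, probability = prob,
                          networkMask = netMask, overlap = overlap)
  }

  diceTable <- NULL
  if (length(radiusMm) > 1L) {
    pairs <- utils::combn(as.character(radiusMm), 2)
    diceTable <- data.frame(
      radius_a = as.numeric(pairs[1, ]), radius_b = as.numeric(pairs[2, ]),
      dice = apply(pairs, 2L, function(pr)
        diceCoefficient(byRadius[[pr[1]]]$networkMask,
                        byRadius[[pr[2]]]$networkMask)))
  }

  list(screening = scr, includedSubjects = included,
       excludedSubjects = excludedSubjects, byRadius = byRadius,
       diceTable = diceTable,
       params = list(radiusMm = radiusMm, q = q, tau = tau,
                     inclusiveTau = inclusiveTau,
                     alternative = alternative,
                     sigThreshold = sigThreshold,
                     fdThresholdMm = fdThresholdMm, lowHz = lowHz,
                     highHz = highHz, fwhmMm = fwhmMm,
                     globalSignal = globalSignal,
                     preprocess = preprocess,
                     maxTransMm = maxTransMm, maxRotDeg = maxRotDeg))
}

#' Seed-radius sensitivity analysis
#'
#' Reruns the pipeline on identical inputs with several sphere radii
#' (default the 1 / 4 / 7 mm settings) and reports the pairwise Dice
#' similarity of the final thresholded masks. A thin convenience over
#' [runFCNM()] with a vector `radiusMm`.
#'
#' @inheritParams runFCNM
#' @param radii radii in mm (default `c(1, 4, 7)`).
#' @param ... passed to [runFCNM()].
#' @return As [runFCNM()]; `diceTable` holds the pairwise comparison.
#' @export
radiusSensitivity <- function(contrasts, subjects, brain,
                              radii = c(1, 4, 7), ...) {
  if (length(radii) < 2L) stop("need at least two radii")
  runFCNM(contrasts, subjects, brain, radiusMm = radii, ...)
}
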