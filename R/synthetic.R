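#' Parameters of the synthetic validation dataset
#'
#' Describes a desk-scale stand-in for a large normative resting-state
#' cohort: a cubic analysis grid, K disjoint ellipsoidal "canonical"
#' networks planted inside an ellipsoidal brain mask, per-subject BOLD
#' series in which every network's voxels share a band-limited latent
#' time course buried in white noise, and motion traces with occasional
#' spikes. The latents are generated inside the 0.01-0.1 Hz analysis
#' band so the filtering stage is exercised without destroying planted
#' signal.
#'
#' @param gridDim grid dimensions (default `c(24, 24, 24)`).
#' @param voxelMm isotropic voxel size (default 3 mm).
#' @param nNetworks number of planted networks K (default 2).
#' @param nSubjects cohort size (default 30).
#' @param nVolumes time points per subject (default 200).
#' @param trSeconds repetition time (default 2 s).
#' @param amplitude network signal amplitude relative to unit-variance
#'   latents (default 0.08). Against unit white noise and after 6 mm
#'   smoothing this yields within-network voxel-to-seed correlations of
#'   roughly 0.4, the magnitude typical of seed-based resting-state FC.
#' @param noiseSd white-noise standard deviation (default 1).
#' @param spikeProb per-volume probability of a motion spike large
#'   enough to exceed FD 0.5 mm (default 0.03).
#' @param brainRadiusMm semi-axis of the spherical brain mask (default
#'   33 mm).
#' @param networkSemiAxesMm semi-axes of each planted network ellipsoid
#'   (default `c(13, 11, 11)` mm).
#' @param networkRingMm radius of the circle (in the z = 0 plane) on
#'   which network centres are placed (default 16 mm).
#' @param tissueZMm height of the white-matter / CSF surrogate spheres
#'   above / below the network plane (default `brainRadiusMm - 12`).
#' @param masterSeed integer master seed; all per-subject and
#'   per-table seeds are derived from it.
#' @return A validated parameter list of class `"syntheticDesign"`.
#' @export
syntheticDesign <- function(gridDim = c(24, 24, 24), voxelMm = 3,
                            nNetworks = 2, nSubjects = 30,
                            nVolumes = 200, trSeconds = 2,
                            amplitude = 0.08, noiseSd = 1,
                            spikeProb = 0.03, brainRadiusMm = 33,
                            networkSemiAxesMm = c(14, 16, 14),
                            networkRingMm = 16, tissueZMm = NULL,
                            masterSeed = 1) {
  stopifnot(nNetworks >= 2, amplitude > 0, noiseSd >= 0,
            spikeProb >= 0, spikeProb < 1, nVolumes >= 2,
            nSubjects >= 3)
  d <- list(grid = volumeGrid(gridDim, voxelMm = voxelMm),
            nNetworks = as.integer(nNetworks),
            nSubjects = as.integer(nSubjects),
            nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
            amplitude = amplitude, noiseSd = noiseSd,
            spikeProb = spikeProb, brainRadiusMm = brainRadiusMm,
            networkSemiAxesMm = rep(networkSemiAxesMm, length.out = 3),
            networkRingMm = networkRingMm,
            tissueZMm = if (is.null(tissueZMm)) brainRadiusMm - 12
                        else tissueZMm,
            masterSeed = as.integer(masterSeed))
  class(d) <- "syntheticDesign"
  d
}

#' @export
print.syntheticDesign <- function(x, ...) {
  cat(sprintf(
    "syntheticDesign: %s grid, %d networks, %d subjects x %d volumes (TR %g s)\n",
    paste(gridDim(x$grid), collapse = "x"), x$nNetworks, x$nSubjects,
    x$nVolumes, x$trSeconds))
  cat(sprintf("  amplitude %g, noise sd %g, spike prob %g, seed %d\n",
              x$amplitude, x$noiseSd, x$spikeProb, x$masterSeed))
  invisible(x)
}

#' Derive a per-subject or per-table seed from a master seed
#'
#' Deterministic 32-bit-safe derivation; index 0 is reserved for the
#' contrast-table seed, indices 1..n for subjects.
#'
#' @param masterSeed integer master seed.
#' @param k derivation index.
#' @return An integer seed.
#' @export
deriveSeed <- function(masterSeed, k) {
  as.integer((as.numeric(masterSeed) * 10007 + k) %% 2147483647)
}

ellipsoidArray <- function(grid, centerMm, semiAxesMm) {
  d <- gridDim(grid)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  mm <- rbind(voxelToMm(idx, grid))
  inside <- ((mm[, 1] - centerMm[1]) / semiAxesMm[1])^2 +
            ((mm[, 2] - centerMm[2]) / semiAxesMm[2])^2 +
            ((mm[, 3] - centerMm[3]) / semiAxesMm[3])^2 <= 1
  array(inside, d)
}

#' Build the synthetic atlas, brain mask, and tissue surrogates
#'
#' Plants K disjoint ellipsoidal networks on a ring in the central
#' axial plane of a spherical brain mask, plus two small spherical
#' regions above and below the ring that serve as white-matter and CSF
#' surrogates for the tissue-mean regressors. Construction is purely
#' geometric, hence deterministic for a given design.
#'
#' @param design a [syntheticDesign()] list.
#' @return List with `atlas` ([CanonicalAtlas-class]), `brain`, `wm`,
#'   `csf` (all [BrainMask-class]).
#' @export
makeAtlas <- function(design) {
  g <- design$grid
  K <- design$nNetworks
  brain <- ellipsoidArray(g, c(0, 0, 0), rep(design$brainRadiusMm, 3))
  labels <- array(0L, gridDim(g))
  centers <- lapply(seq_len(K), function(k) {
    th <- 2 * pi * (k - 1) / K
    design$networkRingMm * c(cos(th), sin(th), 0)
  })
  for (k in seq_len(K)) {
    reg <- ellipsoidArray(g, centers[[k]], design$networkSemiAxesMm)
    if (!any(reg)) stop("network ", k, " is empty on this grid")
    if (any(reg & !brain))
      stop("network ", k, " leaves the brain mask; shrink the extents")
    if (any(labels[reg] != 0L))
      stop("network regions overlap; use smaller extents or a larger ",
           "ring radius")
    labels[reg] <- k
  }
  tissue <- function(zMm) {
    s <- ellipsoidArray(g, c(0, 0, zMm), rep(6, 3))
    if (any(s & labels > 0L) || any(s & !brain))
      stop("tissue surrogate region collides with a network or the ",
           "brain boundary")
    s
  }
  list(atlas = new("CanonicalAtlas", grid = g, labels = labels,
                   networkNames = paste0("network_",
                                         LETTERS[seq_len(K)])),
       brain = brainMask(brain, g),
       wm = brainMask(tissue(design$tissueZMm), g),
       csf = brainMask(tissue(-design$tissueZMm), g))
}

# band-limited unit-variance latent time courses, K x T
makeLatents <- function(K, nVolumes, trSeconds, lowHz = 0.015,
                        highHz = 0.09, nComponents = 30) {
  t <- (seq_len(nVolumes) - 1) * trSeconds
  out <- matrix(0, K, nVolumes)
  for (k in seq_len(K)) {
    f <- stats::runif(nComponents, lowHz, highHz)
    ph <- stats::runif(nComponents, 0, 2 * pi)
    am <- abs(stats::rnorm(nComponents))
    x <- colSums(am * sin(outer(2 * pi * f, t) + ph))
    out[k, ] <- (x - mean(x)) / stats::sd(x)
  }
  out
}

#' Simulate one subject's BOLD run and motion trace
#'
#' Every planted network carries its own band-limited latent time
#' course; a voxel's series is `amplitude * latent(label) + noise`, and
#' background (and tissue-surrogate) voxels are pure noise. The motion
#' trace is a slow random drift plus occasional single-volume jumps of
#' 0.8 mm, large enough to trip the FD > 0.5 mm spike rule while
#' staying far below the 2 mm / 2 degree exclusion limits.
#'
#' @param design a [syntheticDesign()] list.
#' @param world result of [makeAtlas()] for the same design.
#' @param subjectSeed integer seed; identical seeds give byte-identical
#'   output.
#' @return List with `bold` ([Bold4D-class]), `motion` (n-by-6 matrix),
#'   and `latents` (K-by-T matrix, for oracle checks).
#' @export
simulateSubject <- function(design, world, subjectSeed) {
  set.seed(subjectSeed)
  g <- design$grid
  nv <- nVoxels(g)
  Tn <- design$nVolumes
  lat <- makeLatents(design$nNetworks, Tn, design$trSeconds)
  vals <- matrix(stats::rnorm(nv * Tn, sd = design$noiseSd), nv, Tn)
  labs <- as.vector(world$atlas@labels)
  for (k in seq_len(design$nNetworks)) {
    rows <- which(labs == k)
    vals[rows, ] <- vals[rows, ] +
      matrix(design$amplitude * lat[k, ], length(rows), Tn,
             byrow = TRUE)
  }
  motion <- cbind(
    apply(matrix(stats::rnorm(Tn * 3, sd = 0.002), Tn, 3), 2L, cumsum),
    apply(matrix(stats::rnorm(Tn * 3, sd = 4e-5), Tn, 3), 2L, cumsum))
  spikes <- which(stats::runif(Tn) < design$spikeProb)
  spikes <- spikes[spikes > 1L]
  motion[spikes, 1] <- motion[spikes, 1] + 0.8
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  list(bold = bold4D(vals, g, design$trSeconds), motion = motion,
       latents = lat)
}

#' Sample synthetic contrast tables with peaks inside chosen networks
#'
#' Emulates the extracted peak tables of a coordinate-based analysis:
#' each synthetic contrast gets `peaksPerContrast` coordinates drawn
#' from voxel centres carrying the target label (or from in-brain
#' background when the target is 0), with optional uniform mm jitter.
#' Jittered peaks whose nearest voxel leaves the brain mask are
#' redrawn.
#'
#' @param world result of [makeAtlas()].
#' @param targetNetworks integer vector of atlas labels (0 =
#'   background), recycled across contrasts.
#' @param nContrasts number of contrasts (default 6).
#' @param peaksPerContrast peaks per contrast (default 3).
#' @param jitterMm half-width of the uniform jitter (default 2 mm).
#' @param seed integer seed.
#' @param metadata optional data.frame with columns `direction`, `sex`,
#'   `age_group`, `state` (one row per contrast, recycled) used to fill
#'   the subgroup fields.
#' @return Named list of [StudyContrast-class] objects.
#' @export
sampleContrastPeaks <- function(world, targetNetworks = 1,
                                nContrasts = 6, peaksPerContrast = 3,
                                jitterMm = 2, seed = 1,
                                metadata = NULL) {
  set.seed(seed)
  g <- world$atlas@grid
  labs <- as.vector(world$atlas@labels)
  brain <- as.vector(maskValues(world$brain))
  d <- gridDim(g)
  idxAll <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                  z = 0:(d[3] - 1)))
  targets <- rep(targetNetworks, length.out = nContrasts)
  out <- list()
  for (j in seq_len(nContrasts)) {
    tgt <- targets[j]
    pool <- if (tgt == 0) which(brain & labs == 0L)
            else which(labs == tgt)
    if (length(pool) < peaksPerContrast)
      stop("target region ", tgt, " is too small for ",
           peaksPerContrast, " peaks")
    pks <- matrix(NA_real_, peaksPerContrast, 3)
    for (i in seq_len(peaksPerContrast)) {
      repeat {
        v <- idxAll[sample(pool, 1L), ]
        mm <- voxelToMm(v, g) +
          stats::runif(3, -jitterMm, jitterMm)
        nv <- mmToVoxel(mm, g)
        if (all(nv >= 0) && all(nv <= d - 1L) &&
            brain[voxelIndex(nv, g)]) {
          pks[i, ] <- mm
          break
        }
      }
    }
    md <- if (is.null(metadata)) {
      data.frame(direction = "GM_decrease", sex = "unknown",
                 age_group = "unknown", state = "unknown")
    } else metadata[(j - 1L) %% nrow(metadata) + 1L, , drop = FALSE]
    cid <- sprintf("syn%02d.c1", j)
    out[[cid]] <- studyContrast(
      studyId = sprintf("syn%02d", j), contrastId = cid,
      peaks = data.frame(x = pks[, 1], y = pks[, 2], z = pks[, 3],
                         space = "MNI"),
      direction = md$direction, sexFemaleOnly = parseSexFlag(md$sex),
      ageGroup = md$age_group, clinicalState = md$state)
  }
  out
}

#' Write a self-contained synthetic dataset to disk
#'
#' Materialises a full desk-scale study: per-subject 4-D BOLD NIfTI and
#' 6-column motion `.par` files, atlas and mask volumes, a contrasts
#' CSV, and a `design.json` provenance record including every derived
#' seed.
#'
#' @param design a [syntheticDesign()] list.
#' @param dir output directory (created if needed).
#' @param targetNetworks passed to [sampleContrastPeaks()].
#' @param nContrasts,peaksPerContrast,jitterMm passed through.
#' @return The directory path, invisibly.
#' @export
writeSyntheticDataset <- function(design, dir, targetNetworks = 1,
                                  nContrasts = 6, peaksPerContrast = 3,
                                  jitterMm = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  world <- makeAtlas(design)
  writeVolume(world$atlas, file.path(dir, "atlas.nii.gz"))
  writeVolume(world$brain, file.path(dir, "brain_mask.nii.gz"))
  writeVolume(world$wm, file.path(dir, "wm_mask.nii.gz"))
  writeVolume(world$csf, file.path(dir, "csf_mask.nii.gz"))
  tableSeed <- deriveSeed(design$masterSeed, 0L)
  contrasts <- sampleContrastPeaks(world, targetNetworks, nContrasts,
                                   peaksPerContrast, jitterMm,
                                   seed = tableSeed)
  writeContrastTable(contrasts, file.path(dir, "contrasts.csv"))
  subjectSeeds <- vapply(seq_len(design$nSubjects),
                         function(i) deriveSeed(design$masterSeed, i),
                         integer(1))
  for (i in seq_len(design$nSubjects)) {
    subj <- simulateSubject(design, world, subjectSeeds[i])
    writeBold(subj$bold, file.path(dir, sprintf("sub-%02d_bold.nii.gz",
                                                i)))
    utils::write.table(subj$motion,
                       file.path(dir, sprintf("sub-%02d_motion.par", i)),
                       row.names = FALSE, col.names = FALSE)
  }
  prov <- list(gridDim = gridDim(design$grid),
               voxelMm = unname(voxelSizes(design$grid)[1]),
               nNetworks = design$nNetworks,
               nSubjects = design$nSubjects,
               nVolumes = design$nVolumes,
               trSeconds = design$trSeconds,
               amplitude = design$amplitude, noiseSd = design$noiseSd,
               spikeProb = design$spikeProb,
               masterSeed = design$masterSeed, tableSeed = tableSeed,
               subjectSeeds = subjectSeeds,
               targetNetworks = targetNetworks,
               nContrasts = nContrasts,
               peaksPerContrast = peaksPerContrast,
               jitterMm = jitterMm)
  jsonlite::write_json(prov, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
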