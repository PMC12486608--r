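---
title: "Mapping peak coordinates onto functional brain networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peak coordinates onto functional brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structural neuroimaging studies of a clinical population rarely agree on
*where* the brain differs: voxel-based morphometry reports scatter peak
coordinates across many regions. Coordinate-based network mapping asks a
different question — whether those scattered peaks are *functionally
connected* to a common distributed network. The logic is borrowed from
lesion network mapping: each reported peak is treated as a seed, its
resting-state functional connectivity map is computed in a large
normative cohort, and the question becomes whether the per-study maps
converge on the same network.

`coordnet` implements this chain end to end:

1. **Ingest** — read delimited tables of published peaks (study id,
   contrast id, stereotactic space, x/y/z in mm, direction of the
   gray-matter effect, subgroup metadata), convert Talairach-labelled
   rows to MNI, and drop peaks falling outside a gray-matter mask. A
   contrast whose peaks *all* fall outside the mask is excluded, the
   coordinate-level analogue of the usual study-exclusion rule.
2. **Seeds** — centre a sphere (default radius 4 mm) on every peak of a
   contrast, take the union, and intersect it with the brain mask.
3. **Subject-level connectivity** — after confound preprocessing,
   correlate each seed's mean time series with every in-mask voxel and
   apply the Fisher-Z transform, one map per subject and contrast.
4. **Group inference** — a voxelwise one-sample t-test across subjects,
   thresholded at p < 0.05 with voxel-level Benjamini–Hochberg FDR
   control, restricted to positive connectivity, and binarised.
5. **Convergence** — the binarised maps are averaged into a network
   probability map (the voxelwise fraction of contrasts containing the
   voxel), thresholded at 50% to yield the convergent network, and
   quantified against a canonical-network atlas by overlap ratios
   (overlap voxels / canonical in-mask voxels), with ratios ≥ 10%
   flagged as meaningful association.

## Preprocessing model

Inputs are assumed motion-corrected and co-registered to one analysis
grid (a `VolumeGrid`: array dimensions plus a 4×4 voxel-to-mm affine,
0-based indices, RAS mm). The package's stage covers what follows
realignment, in this order:

* **Nuisance regression.** Ordinary least squares per voxel against:
  intercept, centred linear drift, the Friston-24 motion expansion (6
  rigid-body parameters, their one-volume backward differences with a
  zero first row, and the squares of both), one indicator column per
  spike volume (framewise displacement FD > 0.5 mm, strict inequality),
  and mean signals over whichever tissue masks are supplied (global
  brain, white matter, CSF). FD follows the Power convention:
  the sum of absolute backward differences of the translations plus the
  rotations converted to arc length on a 50 mm sphere, with FD = 0 at
  the first volume; motion-file rotations are radians (SPM convention),
  with a degrees option at read time. Exactly duplicated design columns
  are dropped, all-zero columns (a motionless trace's derivatives) are
  removed, and a design that is still rank deficient is an error naming
  the collinear columns, never a silent pseudo-inverse.
* **Band-pass filtering**, 0.01–0.1 Hz. A 4th-order Butterworth is
  designed for the series' sampling rate and its zero-phase
  (squared-magnitude, i.e. forward–backward) response is applied in the
  frequency domain to all voxels at once. DC is removed exactly;
  mid-band gain is within a few percent of unity. The frequency-domain
  application assumes circular continuation of the (already detrended,
  demeaned) residual series; for the band and series lengths used here
  the edge effect is negligible away from the first and last few
  volumes.
* **Spatial smoothing**, Gaussian, FWHM 6 mm by default
  (σ = FWHM / (2√(2 ln 2)) per axis, in mm converted to voxels through
  the affine), separable, zero-padded at the grid boundary, applied
  volume by volume. FWHM 0 is the identity.

Subjects whose motion trace reaches 2 mm translation or 2° rotation are
excluded from group stacking before any regression.

The ordering — regression, then filtering, then smoothing — mirrors the
narrative order of typical pipelines. Sequential regression-then-
filtering can reintroduce a small amount of filtered-band nuisance
variance compared with a simultaneous band-limited regression; the
simultaneous variant is deliberately not implemented, and users should
be aware of the choice.

## Statistical decisions

* **Sidedness.** The pipeline tests positive connectivity only.
  The default computes one-sided upper-tail p values and applies FDR to
  those; a `two.sided` variant (two-sided FDR family, then positive-t
  masking) is available because published descriptions are frequently
  ambiguous between the two. The two variants differ only in the FDR
  family's p values, not in the positivity restriction.
* **FDR procedure.** Benjamini–Hochberg step-up over the in-mask voxels
  of one contrast map (per-contrast family): sort p ascending, find the
  largest k with p(k) ≤ k·q/m, reject everything at or below p(k). The
  realised threshold is reported in each map's sidecar. BH is the
  classical "voxel-level FDR" reading; no adaptive or dependency-
  corrected variant is attempted.
* **Degenerate voxels.** Zero across-subject spread with positive mean
  gives p = 0 (t reported infinite); zero spread with zero mean gives
  t = 0, p = 0.5 one-sided. Zero-variance time series yield r = 0 with
  a logged count rather than NaN, and |r| is clipped to 1 − 10⁻⁷ before
  `atanh` so perfectly correlated voxels map to finite z ≈ 8.4.
* **Probability threshold.** "More than 50% of the contrast seeds" is
  read strictly: a voxel present in exactly half the maps is excluded.
  An inclusive `>=` flag exists because "thresholded at 50%" alone is
  ambiguous. Comparisons use an epsilon guard of 10⁻¹² around exact
  k/n fractions.
* **Overlap denominators** are canonical-network voxels *inside the
  analysis brain mask*, so atlas voxels with no data cannot dilute the
  ratio.

## Coordinate handling

* Voxel indices are 0-based; mm-to-voxel conversion applies the inverse
  affine and rounds half away from zero.
* Talairach → MNI uses the classical piecewise-affine pair
  T = R_x(0.05 rad) · diag(0.99, 0.97, s), with s = 0.92 above the AC
  plane and 0.84 below, no translation. The forward (MNI → Talairach)
  direction selects the branch on the sign of MNI z. The inverse tries
  the z ≥ 0 branch first and falls back to the other branch when the
  candidate's MNI z is negative, which makes the round trip exactly
  self-consistent everywhere except a sliver (≲ 0.3 mm thick) near the
  AC plane where the two branches genuinely disagree. The matrix pair
  is a plug-in argument (`matrices =`), since the exact tool used by
  any given source study is generally unknowable.
* **Sphere membership** is a closed ball on voxel centres (distance
  from centre ≤ radius, with a 10⁻⁹ guard for exact-boundary
  arithmetic). When merging a contrast's spheres, each peak additionally
  contributes the voxel containing it: with a radius below the voxel
  spacing (the 1 mm sensitivity setting on a 3 mm lattice) a pure
  closed ball around an off-centre coordinate is frequently empty, and
  the peak would vanish from its own seed. `buildSphere` itself keeps
  the pure geometric contract.

## The synthetic cohort

Real normative cohorts are thousands of scans; the generator
(`syntheticDesign()`, `makeAtlas()`, `simulateSubject()`,
`sampleContrastPeaks()`, `writeSyntheticDataset()`) stands in for them
at desk scale with the statistical structure the analysis actually
relies on:

* a 24³ grid of 3 mm voxels; a spherical brain mask (radius 33 mm);
  K = 2 disjoint ellipsoidal "canonical" networks (semi-axes
  14 × 16 × 14 mm, ≈ 480 voxels each) on a 16 mm ring, plus two small
  spheres above and below the network plane serving as white-matter and
  CSF surrogates;
* 30 subjects × 200 volumes at TR 2 s; each network has a per-subject
  latent time course synthesised inside 0.015–0.09 Hz (so the band-pass
  stage is exercised without destroying planted signal); a voxel's
  series is `amplitude × latent(label) + white noise`;
* motion traces are slow random drifts plus occasional 0.8 mm
  single-volume jumps — large enough to trip the FD > 0.5 mm spike rule,
  far below the 2 mm exclusion limit;
* contrast tables sample peaks from voxel centres of a target network
  (or from background, for null calibration), with uniform mm jitter,
  redrawn if jitter leaves the brain mask.

**Amplitude calibration.** The free parameters were set so that the
*observed* connectivity matches what seed-based resting-state analyses
actually see: with amplitude 0.08 against unit noise, 6 mm smoothing
yields within-network voxel-to-seed correlations around 0.4. This
matters for the recovery property: smoothing spreads planted signal
into a 1–2 voxel halo around a network, and with 30 subjects the group
test detects any halo voxel whose correlation clears the FDR threshold.
At high raw amplitude the halo is detected wholesale and the recovered
mask dilates far beyond the planted network; at the calibrated
amplitude the halo falls below threshold while the network core remains
unambiguous, so the final mask tracks the planted truth (Dice well
above 0.7 in the packaged tests) and background-seeded runs come back
empty. Global-signal regression also induces the familiar negative
correlations between the two planted networks, which the positive-only
inference discards — a deliberate miniature of the real analysis
situation.

What the generator does **not** emulate: hemodynamic response shapes,
spatially correlated physiological noise, multiband acquisition
timing, anatomical tissue geometry, or inter-subject anatomical
variability. Passing the planted-truth tests therefore demonstrates
that the pipeline's logic and statistics are correct, not that any
particular real-data effect size will be recovered.

## Problem sizes in the packaged tests

Unit tests run on grids up to 15³ with a 16³ × 6-subject × 80-volume
miniature cohort; the end-to-end validation tests run the generator's
full default design (24³, 30 subjects, 200 volumes, 6 contrasts) across
five master seeds for recovery and five for null calibration, plus a
three-radius (1/4/7 mm) sensitivity run; determinism is exercised on
the miniature cohort through the full configuration-file interface.
These sizes were chosen so the complete suite exercises every stage at
the design's stated scale while remaining runnable on a laptop.

## Known limitations

* The FDR family is per contrast; no across-contrast correction is
  attempted (matching standard practice for this design).
* Group inference has no covariates — subject age/sex modelling is out
  of scope.
* Negative-connectivity networks are deliberately not produced.
* The atlas is a user input resampled by nearest neighbour; the package
  claims no correspondence between its synthetic atlas and any
  published parcellation.
* Cluster-extent statistics, anatomical labelling, and figure-quality
  renderings are out of scope; outputs are NIfTI volumes and CSV/JSON
  tables.
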