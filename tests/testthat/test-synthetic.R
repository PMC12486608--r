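test_that("the synthetic atlas is deterministic, disjoint, and in-brain", {
  d <- smallDesign()
  w1 <- makeAtlas(d)
  w2 <- makeAtlas(d)
  expect_identical(atlasLabels(w1$atlas), atlasLabels(w2$atlas))
  expect_identical(maskValues(w1$brain), maskValues(w2$brain))

  labs <- atlasLabels(w1$atlas)
  expect_equal(sort(unique(as.vector(labs))), 0:2)
  expect_true(all(labs[!maskValues(w1$brain)] == 0L))
  expect_gt(sum(labs == 1L), 0)
  expect_gt(sum(labs == 2L), 0)
  # tissue surrogates never overlap networks
  expect_false(any(maskValues(w1$wm) & labs > 0L))
  expect_false(any(maskValues(w1$csf) & labs > 0L))

  big <- smallDesign()
  big$networkSemiAxesMm <- c(14, 14, 14)
  expect_error(makeAtlas(big), "overlap|brain")
})

test_that("simulated subjects have planted within-network coherence", {
  d <- smallDesign()
  w <- smallWorld(d)

  s1 <- simulateSubject(d, w, subjectSeed = 101)
  s2 <- simulateSubject(d, w, subjectSeed = 101)
  expect_identical(boldMatrix(s1$bold), boldMatrix(s2$bold))
  expect_identical(s1$motion, s2$motion)
  s3 <- simulateSubject(d, w, subjectSeed = 102)
  expect_false(identical(boldMatrix(s1$bold), boldMatrix(s3$bold)))

  # noiseless: voxels of one network are perfectly correlated, and
  # cross-network correlation equals the latents' sample correlation
  d0 <- smallDesign()
  d0$noiseSd <- 0
  s0 <- simulateSubject(d0, w, subjectSeed = 103)
  labs <- as.vector(atlasLabels(w$atlas))
  v1 <- which(labs == 1L)[1:2]
  v2 <- which(labs == 2L)[1]
  m <- boldMatrix(s0$bold)
  expect_equal(cor(m[v1[1], ], m[v1[2], ]), 1)
  expect_equal(cor(m[v1[1], ], m[v2, ]),
               cor(s0$latents[1, ], s0$latents[2, ]))

  # motion spikes exceed the FD threshold; limits still pass
  fd <- computeFD(s1$motion)
  expect_gt(max(fd), 0.5)
  expect_true(checkMotionLimits(s1$motion)$pass)
})

test_that("sampled contrast peaks land in their target network", {
  d <- smallDesign()
  w <- smallWorld(d)
  cs <- sampleContrastPeaks(w, targetNetworks = c(1, 2), nContrasts = 4,
                            peaksPerContrast = 3, jitterMm = 0,
                            seed = 5)
  expect_length(cs, 4L)
  labs <- atlasLabels(w$atlas)
  g <- w$atlas@grid
  for (j in seq_along(cs)) {
    pk <- peakTable(cs[[j]])
    expect_equal(nrow(pk), 3L)
    tgt <- c(1, 2, 1, 2)[j]
    for (i in 1:3) {
      v <- mmToVoxel(unlist(pk[i, 1:3], use.names = FALSE), g)
      expect_equal(labs[v[1] + 1, v[2] + 1, v[3] + 1], tgt)
    }
  }
  cs2 <- sampleContrastPeaks(w, targetNetworks = c(1, 2), nContrasts = 4,
                             peaksPerContrast = 3, jitterMm = 0,
                             seed = 5)
  expect_identical(lapply(cs, peakTable), lapply(cs2, peakTable))

  # jittered peaks always stay inside the brain mask
  cs3 <- sampleContrastPeaks(w, 0, nContrasts = 6, jitterMm = 3,
                             seed = 6)
  brain <- maskValues(w$brain)
  for (sc in cs3) {
    pk <- as.matrix(peakTable(sc)[, 1:3])
    for (i in seq_len(nrow(pk))) {
      v <- mmToVoxel(pk[i, ], g)
      expect_true(brain[v[1] + 1, v[2] + 1, v[3] + 1])
    }
  }
})

test_that("a written dataset is self-contained and reproducible", {
  d <- smallDesign()
  d$nSubjects <- 2L
  dir1 <- file.path(tempdir(), "synds1")
  dir2 <- file.path(tempdir(), "synds2")
  writeSyntheticDataset(d, dir1, nContrasts = 2)
  writeSyntheticDataset(d, dir2, nContrasts = 2)
  need <- c("atlas.nii.gz", "brain_mask.nii.gz", "wm_mask.nii.gz",
            "csf_mask.nii.gz", "contrasts.csv", "design.json",
            "sub-01_bold.nii.gz", "sub-01_motion.par")
  expect_true(all(file.exists(file.path(dir1, need))))
  for (f in need)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  prov <- jsonlite::read_json(file.path(dir1, "design.json"))
  expect_equal(prov$masterSeed, d$masterSeed)
  expect_length(prov$subjectSeeds, 2L)

  # the round trip through NIfTI + CSV reloads cleanly
  b <- readBold(file.path(dir1, "sub-01_bold.nii.gz"))
  expect_equal(repetitionTime(b), d$trSeconds)
  expect_equal(gridDim(b), gridDim(d$grid))
  cs <- readContrastTable(file.path(dir1, "contrasts.csv"))
  expect_length(cs, 2L)
  m <- readMotionFile(file.path(dir1, "sub-01_motion.par"))
  expect_equal(nrow(m), d$nVolumes)
})
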