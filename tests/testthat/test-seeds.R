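# independent oracle: brute-force scan of every voxel centre
bruteSphere <- function(centerMm, radiusMm, grid) {
  d <- gridDim(grid)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  mm <- voxelToMm(idx, grid)
  keep <- sqrt(rowSums(sweep(mm, 2, centerMm)^2)) <= radiusMm + 1e-9
  out <- array(FALSE, d)
  out[voxelIndex(idx[keep, , drop = FALSE], grid)] <- TRUE
  out
}
voxelIndex <- coordnet:::voxelIndex

test_that("sphere voxel sets match brute-force enumeration at radii 1/4/7 on a 3 mm grid", {
  g <- tinyGrid(15)
  ctr <- voxelToMm(c(7, 7, 7), g)
  counts <- c()
  for (r in c(1, 4, 7)) {
    sph <- buildSphere(ctr, r, g)
    expect_identical(sph, bruteSphere(ctr, r, g))
    counts <- c(counts, sum(sph))
  }
  # centre only; centre + 6 face neighbours (diagonals at 4.243 mm out);
  # r=7 includes the 6.708 mm offsets but not 7.348 mm
  expect_equal(counts[1], 1)
  expect_equal(counts[2], 7)
  expect_true(all(diff(counts) > 0))
})

test_that("sphere membership equals brute force on random affine grids", {
  set.seed(11)
  for (i in 1:5) {
    a <- diag(c(stats::runif(3, 2, 4), 1))
    a[1:3, 4] <- stats::runif(3, -30, 0)
    g <- volumeGrid(sample(8:14, 3, replace = TRUE), affine = a)
    ctr <- stats::runif(3, -15, 10)
    r <- stats::runif(1, 2, 9)
    expect_identical(buildSphere(ctr, r, g), bruteSphere(ctr, r, g))
  }
})

test_that("seed voxel count is non-decreasing in radius", {
  g <- tinyGrid(15)
  mask <- fullMask(g)
  ctr <- voxelToMm(c(7, 7, 7), g) + c(1.2, -0.7, 0.4)
  sc <- studyContrast("S", "S.c1", data.frame(
    x = ctr[1], y = ctr[2], z = ctr[3], space = "MNI"))
  sizes <- vapply(c(1, 4, 7), function(r)
    sum(maskValues(buildSeedMask(sc, r, g, mask))), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  s1 <- maskValues(buildSeedMask(sc, 1, g, mask))
  s4 <- maskValues(buildSeedMask(sc, 4, g, mask))
  s7 <- maskValues(buildSeedMask(sc, 7, g, mask))
  expect_true(all(s4[s1]))    # nesting, not just counts
  expect_true(all(s7[s4]))
})

test_that("merged seeds are unions intersected with the brain mask", {
  g <- volumeGrid(c(24, 12, 12), voxelMm = 3)
  mask <- fullMask(g)
  c1 <- voxelToMm(c(4, 6, 6), g)
  c2 <- c1 + c(30, 0, 0)   # 30 mm apart: spheres disjoint at r = 4
  two <- studyContrast("S", "S.c1", data.frame(
    x = c(c1[1], c2[1]), y = c(c1[2], c2[2]), z = c(c1[3], c2[3]),
    space = "MNI"))
  seed <- buildSeedMask(two, 4, g, mask)
  expect_equal(sum(maskValues(seed)),
               sum(buildSphere(c1, 4, g)) + sum(buildSphere(c2, 4, g)))

  dup <- studyContrast("S", "S.c2", data.frame(
    x = rep(c1[1], 2), y = rep(c1[2], 2), z = rep(c1[3], 2),
    space = "MNI"))
  expect_equal(sum(maskValues(buildSeedMask(dup, 4, g, mask))),
               sum(buildSphere(c1, 4, g)))

  # near the mask boundary every seed voxel stays inside the mask
  half <- array(FALSE, gridDim(g)); half[1:5, , ] <- TRUE
  hm <- brainMask(half, g)
  near <- studyContrast("S", "S.c3", data.frame(
    x = voxelToMm(c(4, 6, 6), g)[1], y = c1[2], z = c1[3],
    space = "MNI"))
  sv <- maskValues(buildSeedMask(near, 4, g, hm))
  expect_true(all(half[sv]))
  expect_lt(sum(sv), sum(buildSphere(voxelToMm(c(4, 6, 6), g), 4, g)))
})

test_that("degenerate spheres warn or error as contracted", {
  g <- tinyGrid(9)
  expect_warning(out <- buildSphere(c(500, 500, 500), 4, g),
                 "outside the grid")
  expect_false(any(out))
  far <- studyContrast("S", "S.c1", data.frame(
    x = 500, y = 500, z = 500, space = "MNI"))
  expect_error(suppressWarnings(buildSeedMask(far, 4, g, fullMask(g))),
               "S.c1")
})
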