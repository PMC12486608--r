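test_that("framewise displacement follows the 50 mm rotation conversion", {
  m <- matrix(0.3, 8, 6)
  expect_equal(computeFD(m), rep(0, 8))

  m2 <- matrix(0, 6, 6); m2[4, 1] <- 0.5
  fd <- computeFD(m2)
  expect_equal(fd[4], 0.5)      # translation step in
  expect_equal(fd[5], 0.5)      # and back out
  expect_equal(fd[c(1:3, 6)], rep(0, 4))

  m3 <- matrix(0, 4, 6); m3[2:4, 5] <- 0.01
  expect_equal(computeFD(m3)[2], 0.5)   # 0.01 rad x 50 mm
  expect_equal(computeFD(m3)[3], 0)

  expect_error(computeFD(matrix(0, 1, 6)), "2 volumes")
  expect_error(computeFD(matrix(0, 5, 4)), "6 columns")
})

test_that("gross-motion limits flag translations >= 2 mm and rotations >= 2 deg", {
  expect_true(checkMotionLimits(matrix(0, 10, 6))$pass)

  m <- matrix(0, 10, 6); m[7, 2] <- 2.5
  res <- checkMotionLimits(m)
  expect_false(res$pass)
  expect_equal(res$failingVolumes, 7L)

  m2 <- matrix(0, 10, 6); m2[3, 4] <- 0.04    # 0.04 rad ~ 2.29 deg
  res2 <- checkMotionLimits(m2)
  expect_false(res2$pass)
  expect_equal(res2$maxRotationDeg, 0.04 * 180 / pi)

  m3 <- matrix(0, 10, 6); m3[3, 4] <- 0.03    # ~1.72 deg: within limits
  expect_true(checkMotionLimits(m3)$pass)
})

test_that("Friston expansion has 24 columns built from params, diffs, and squares", {
  set.seed(3)
  m <- matrix(rnorm(60), 10, 6)
  f <- friston24(m)
  expect_equal(ncol(f), 24L)
  expect_equal(f[, 1:6], m, ignore_attr = TRUE)
  expect_equal(f[, 7:12], rbind(0, diff(m)), ignore_attr = TRUE)
  expect_equal(f[, 13:18], m^2, ignore_attr = TRUE)
  expect_equal(f[, 19:24], rbind(0, diff(m))^2, ignore_attr = TRUE)

  expect_true(all(friston24(matrix(0, 5, 6)) == 0))
  fc <- friston24(matrix(0.7, 5, 6))
  expect_true(all(fc[, 7:12] == 0) && all(fc[, 19:24] == 0))
  expect_true(all(fc[, 1:6] == 0.7))
})

test_that("spike regressors mark exactly the FD > 0.5 volumes", {
  s <- spikeRegressors(c(0, 0.2, 0.7, 0.1))
  expect_equal(dim(s), c(4L, 1L))
  expect_equal(s[, 1], c(0, 0, 1, 0))

  expect_equal(ncol(spikeRegressors(c(0, 0.3, 0.5, 0.2))), 0L)  # strict >
  s2 <- spikeRegressors(c(0, 0.6, 0.2, 0.9))
  expect_equal(ncol(s2), 2L)
  expect_equal(colSums(s2), c(spike_2 = 1, spike_4 = 1))
})

test_that("tissue mean series averages in-mask voxels per volume", {
  g <- tinyGrid(4)
  n <- nVoxels(g)
  vals <- matrix(seq_len(n * 3), n, 3)
  bold <- bold4D(vals, g, 2)
  expect_equal(tissueMeanSeries(bold, fullMask(g)), colMeans(vals))

  one <- array(FALSE, gridDim(g)); one[2, 3, 1] <- TRUE
  idx <- which(as.vector(one))
  expect_equal(tissueMeanSeries(bold, brainMask(one, g)), vals[idx, ])

  two <- array(FALSE, gridDim(g)); two[1:2, 1, 1] <- TRUE
  expect_equal(tissueMeanSeries(bold, brainMask(two, g)),
               (vals[1, ] + vals[2, ]) / 2)
})

test_that("confound regression yields residuals orthogonal to the design", {
  set.seed(5)
  g <- tinyGrid(5)
  n <- 40
  bold <- bold4D(matrix(rnorm(nVoxels(g) * n), ncol = n), g, 2)
  motion <- cbind(matrix(rnorm(n * 3, sd = 0.02), n, 3),
                  matrix(rnorm(n * 3, sd = 2e-4), n, 3))
  motion[10, 1] <- motion[10, 1] + 1      # one spike
  X <- confoundDesign(motion, bold, globalMask = fullMask(g))
  expect_true("global" %in% colnames(X))
  expect_true(any(grepl("spike", colnames(X))))
  res <- regressConfounds(bold, X)
  R <- boldMatrix(res)
  for (j in seq_len(ncol(X))) {
    dots <- abs(R %*% X[, j])
    norms <- sqrt(rowSums(R^2)) * sqrt(sum(X[, j]^2))
    expect_true(all(dots <= 1e-8 * pmax(norms, 1)))
  }
  # residual variance never exceeds input variance
  v0 <- apply(boldMatrix(bold), 1L, var)
  v1 <- apply(R, 1L, var)
  expect_true(all(v1 <= v0 + 1e-12))
})

test_that("regression handles special designs as contracted", {
  g <- tinyGrid(3)
  n <- 30
  set.seed(8)
  vals <- matrix(rnorm(nVoxels(g) * n), ncol = n)
  X <- cbind(a = rnorm(n))
  vals[5, ] <- 3 * X[, 1] + 2          # a voxel equal to a design column
  bold <- bold4D(vals, g, 2)
  res <- regressConfounds(bold, X)
  expect_lt(max(abs(boldMatrix(res)[5, ])), 1e-10)

  # intercept-only design demeans
  resI <- regressConfounds(bold, matrix(1, n, 1,
                                        dimnames = list(NULL, "intercept")))
  expect_equal(boldMatrix(resI), vals - rowMeans(vals),
               ignore_attr = TRUE)

  # rank-deficient after duplicate dropping -> error naming columns
  Xbad <- cbind(a = X[, 1], b = 2 * X[, 1])
  expect_error(regressConfounds(bold, Xbad), "rank deficient")

  expect_error(regressConfounds(bold, matrix(1, n + 1, 1)), "rows")
})
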