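# exhaustive-k oracle for the BH step-up rule
bhOracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0) rep(FALSE, m) else p <= ps[kmax]
}

test_that("one-sample t matches the textbook formula and t.test", {
  res <- oneSampleT(matrix(c(1, 2, 3), 1, 3))
  expect_equal(res$t[1], 3.4641, tolerance = 1e-4)
  expect_equal(res$dof, 2)
  expect_equal(res$p[1], 0.0371, tolerance = 1e-3)

  z <- oneSampleT(matrix(0, 2, 5))
  expect_equal(z$t, c(0, 0))
  expect_equal(z$p, c(0.5, 0.5))

  cst <- oneSampleT(matrix(5, 1, 4))
  expect_equal(cst$p[1], 0)
  expect_true(is.infinite(cst$t[1]))

  expect_error(oneSampleT(matrix(1, 4, 2)), "3 subjects")

  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n, mean = runif(1, -0.5, 0.5))
    mine <- oneSampleT(matrix(x, 1, n))
    ref <- stats::t.test(x, alternative = "greater")
    expect_equal(mine$t[1], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p[1], ref$p.value, tolerance = 1e-10)
    ref2 <- stats::t.test(x)
    mine2 <- oneSampleT(matrix(x, 1, n), alternative = "two.sided")
    expect_equal(mine2$p[1], ref2$p.value, tolerance = 1e-10)
  }
})

test_that("BH step-up matches the hand-worked examples", {
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04), 0.05)$rejected,
               rep(TRUE, 4))
  expect_equal(fdrBH(c(0.001, 0.5), 0.05)$rejected, c(TRUE, FALSE))
  r <- fdrBH(c(0.9, 0.8), 0.05)
  expect_equal(r$rejected, c(FALSE, FALSE))
  expect_true(is.na(r$threshold))
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with the exhaustive oracle and with p.adjust", {
  set.seed(14)
  for (i in 1:300) {
    m <- sample(1:200, 1)
    p <- switch(sample(3, 1),
                runif(m),
                rbeta(m, 0.3, 4),            # enriched small p
                round(runif(m), 2))          # ties
    q <- sample(c(0.01, 0.05, 0.1), 1)
    mine <- fdrBH(p, q)
    expect_identical(mine$rejected, bhOracle(p, q))
    expect_identical(mine$rejected,
                     unname(stats::p.adjust(p, "BH") <= q))
  }
})

test_that("BH controls the family-wise chance of any rejection under the null", {
  set.seed(15)
  reps <- 500; m <- 100
  any_rej <- vapply(seq_len(reps), function(i)
    fdrBH(runif(m), 0.05)$nRejected > 0, logical(1))
  # under a global null P(any rejection) <= q; allow 3 binomial SEs
  expect_lte(mean(any_rej), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("group maps are positive-t, FDR-rejected, in-mask voxels only", {
  set.seed(16)
  g <- tinyGrid(5)
  n <- nVoxels(g)
  nsub <- 20
  stack <- matrix(rnorm(n * nsub, sd = 0.3), n, nsub)
  stack[1:20, ] <- stack[1:20, ] + 1      # strong positive voxels
  stack[21:30, ] <- stack[21:30, ] - 1    # strong negative voxels
  mask <- fullMask(g)
  gm <- groupNetworkMap(stack, mask, contrastId = "c1", q = 0.05)
  expect_true(all(binaryMap(gm)[1:20]))
  expect_false(any(binaryMap(gm)[21:30]))          # negative excluded
  expect_true(all(tValues(gm)[binaryMap(gm)] > 0))

  # two-sided variant also excludes negative voxels via the t > 0 gate
  gm2 <- groupNetworkMap(stack, mask, q = 0.05,
                         alternative = "two.sided")
  expect_false(any(binaryMap(gm2)[21:30]))
  expect_true(all(binaryMap(gm2)[1:20]))

  # binary is a subset of the rejection set
  expect_lte(sum(binaryMap(gm)), sum(pValues(gm) <= gm@pThreshold))

  # pure-noise stack: typically nothing survives; binary never has t <= 0
  noise <- matrix(rnorm(n * nsub), n, nsub)
  gmN <- groupNetworkMap(noise, mask, q = 0.05)
  expect_true(all(tValues(gmN)[binaryMap(gmN)] > 0))
})

test_that("adding the mean map as a subject preserves the t-sign pattern", {
  set.seed(17)
  stack <- matrix(rnorm(50 * 10), 50, 10)
  t1 <- oneSampleT(stack)$t
  stack2 <- cbind(stack, rowMeans(stack))
  t2 <- oneSampleT(stack2)$t
  expect_equal(sign(t1), sign(t2))
})
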