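test_that("contrast tables group rows by (study, contrast) in file order", {
  tf <- writeTestTable(c(
    contrastHeader,
    "S1,S1.c1,MNI,10,-20,30,GM_decrease,female_only,adult,acute",
    "S1,S1.c1,MNI,-8,14,2,GM_decrease,female_only,adult,acute",
    "S2,S2.c1,Talairach,5,5,5,GM_increase,mixed,adolescent,recovered"))
  cs <- readContrastTable(tf)
  expect_length(cs, 2L)
  expect_equal(nrow(peakTable(cs[["S1.c1"]])), 2L)
  expect_equal(nrow(peakTable(cs[["S2.c1"]])), 1L)
  expect_equal(peakTable(cs[["S1.c1"]])$x, c(10, -8))
  # Talairach label survives ingest for later conversion
  expect_equal(peakTable(cs[["S2.c1"]])$space, "Talairach")
  expect_true(isTRUE(cs[["S1.c1"]]@sexFemaleOnly))
  expect_false(isTRUE(cs[["S2.c1"]]@sexFemaleOnly))
  expect_equal(cs[["S2.c1"]]@direction, "GM_increase")
})

test_that("table schema and coordinate errors are specific", {
  noCol <- writeTestTable(c(
    "study,contrast,space,x,y,z,direction,sex,age_group",
    "S1,S1.c1,MNI,1,2,3,GM_decrease,mixed,adult"))
  expect_error(readContrastTable(noCol), "state")
  badNum <- writeTestTable(c(
    contrastHeader,
    "S1,S1.c1,MNI,1,2,3,GM_decrease,mixed,adult,acute",
    "S1,S1.c1,MNI,abc,2,3,GM_decrease,mixed,adult,acute"))
  expect_error(readContrastTable(badNum), "line 3")
  empty <- writeTestTable(contrastHeader)
  expect_error(readContrastTable(empty), "empty")
  badSpace <- writeTestTable(c(
    contrastHeader,
    "S1,S1.c1,Mars,1,2,3,GM_decrease,mixed,adult,acute"))
  expect_error(readContrastTable(badSpace), "space")
})

test_that("parse -> serialise -> parse round trip is lossless", {
  tf <- writeTestTable(c(
    contrastHeader,
    "S1,S1.c1,MNI,10.5,-20,30,GM_decrease,female_only,adult,acute",
    "S1,S1.c2,Talairach,-4,8,-12,GM_increase,mixed,adolescent,chronic"))
  cs1 <- readContrastTable(tf)
  tf2 <- tempfile(fileext = ".csv")
  writeContrastTable(cs1, tf2)
  cs2 <- readContrastTable(tf2)
  expect_equal(names(cs1), names(cs2))
  for (id in names(cs1)) {
    expect_equal(peakTable(cs1[[id]]), peakTable(cs2[[id]]),
                 ignore_attr = TRUE)
    for (sl in c("studyId", "direction", "sexFemaleOnly", "ageGroup",
                 "clinicalState"))
      expect_equal(slot(cs1[[id]], sl), slot(cs2[[id]], sl))
  }
})

test_that("Talairach matrices match the hand-applied closed form", {
  # z >= 0 branch: T = R_x(0.05 rad) %*% diag(0.99, 0.97, 0.92)
  a <- 0.05
  up <- diag(4)
  up[2:3, 2:3] <- rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  up <- up %*% diag(c(0.99, 0.97, 0.92, 1))
  dn <- diag(4)
  dn[2:3, 2:3] <- rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  dn <- dn %*% diag(c(0.99, 0.97, 0.84, 1))

  # no translation: the origin is a fixed point
  expect_equal(talairachToMni(c(0, 0, 0)), c(0, 0, 0))

  # hand-apply the inverse of the published z>=0 matrix
  p <- c(12, -34, 26)
  expect_equal(talairachToMni(p), solve(up, c(p, 1))[1:3],
               tolerance = 1e-12, ignore_attr = TRUE)

  # a z < 0 point routes through the z<0 matrix, and the two branches
  # genuinely differ there
  q <- c(10, 20, -20)
  viaDown <- solve(dn, c(q, 1))[1:3]
  viaUp <- solve(up, c(q, 1))[1:3]
  expect_equal(talairachToMni(q), viaDown, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(max(abs(viaDown - viaUp)), 0.5)

  # forward direction classifies on the MNI z sign
  m <- c(10, 20, -20)
  expect_equal(mniToTalairach(m), (dn %*% c(m, 1))[1:3],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("MNI -> Talairach -> MNI round trip is tight over +/-70 mm", {
  set.seed(42)
  pts <- matrix(stats::runif(300, -70, 70), ncol = 3)
  back <- talairachToMni(mniToTalairach(pts))
  expect_lt(max(abs(back - pts)), 0.1)
})

test_that("peaksToMni converts only Talairach rows", {
  sc <- studyContrast("S", "S.c1",
                      data.frame(x = c(10, 10), y = c(5, 5),
                                 z = c(30, 30),
                                 space = c("MNI", "Talairach")))
  out <- peaksToMni(sc)
  pk <- peakTable(out)
  expect_true(all(pk$space == "MNI"))
  expect_equal(unlist(pk[1, 1:3], use.names = FALSE), c(10, 5, 30))
  expect_false(isTRUE(all.equal(unlist(pk[2, 1:3], use.names = FALSE),
                                c(10, 5, 30))))
})

test_that("mm/voxel conversion applies the inverse affine then rounds half away from zero", {
  gId <- volumeGrid(c(10, 10, 10), affine = diag(4))
  expect_equal(mmToVoxel(c(0, 0, 0), gId), c(0, 0, 0))
  expect_equal(mmToVoxel(c(1.4, 0, 0), gId), c(1, 0, 0))
  expect_equal(mmToVoxel(c(1.5, -1.5, 2.5), gId), c(2, -2, 3))
  a <- diag(c(3, 3, 3, 1)); a[1:3, 4] <- c(-90, -126, -72)
  g3 <- volumeGrid(c(61, 73, 61), affine = a)
  expect_equal(mmToVoxel(c(0, 0, 0), g3), c(30, 42, 24))
  expect_equal(voxelToMm(c(30, 42, 24), g3), c(0, 0, 0))
})

test_that("peak screening drops out-of-mask peaks and excludes empty contrasts", {
  g <- tinyGrid(9)
  vals <- array(FALSE, gridDim(g)); vals[4:6, 4:6, 4:6] <- TRUE
  mask <- brainMask(vals, g)
  insideMm <- voxelToMm(c(4, 4, 4), g)
  inside2 <- voxelToMm(c(5, 5, 5), g)
  outsideMm <- voxelToMm(c(0, 0, 0), g)
  sc <- studyContrast("S", "S.c1", data.frame(
    x = c(insideMm[1], inside2[1], outsideMm[1]),
    y = c(insideMm[2], inside2[2], outsideMm[2]),
    z = c(insideMm[3], inside2[3], outsideMm[3]), space = "MNI"))
  expect_warning(res <- screenPeaks(list(sc), mask), "dropped 1 peak")
  expect_equal(res$report$kept, 2L)
  expect_equal(res$report$dropped, 1L)
  expect_false(res$report$excluded)

  allOut <- studyContrast("S2", "S2.c1", data.frame(
    x = outsideMm[1], y = outsideMm[2], z = outsideMm[3], space = "MNI"))
  res2 <- suppressWarnings(screenPeaks(list(allOut), mask))
  expect_equal(res2$excluded, "S2.c1")
  expect_length(res2$contrasts, 0L)

  allIn <- studyContrast("S3", "S3.c1", data.frame(
    x = insideMm[1], y = insideMm[2], z = insideMm[3], space = "MNI"))
  res3 <- screenPeaks(list(allIn), mask)
  expect_equal(res3$report$dropped, 0L)
  expect_equal(nrow(peakTable(res3$contrasts[[1]])), 1L)

  # screening never increases the peak count
  expect_lte(res$report$kept[1], nrow(peakTable(sc)))
})
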