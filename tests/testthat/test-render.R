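test_that("track accumulation rasterizes segments and sums velocities", {
  g <- imagingGrid(c(0, 0, 0), 0.01, c(10L, 10L, 10L))
  # one straight segment spanning 5 voxels along x
  tr <- data.frame(track_id = 1L, frame = 1:2,
                   z_mm = 0.05, x_mm = c(0.01, 0.05), y_mm = 0.05,
                   vz_mm_s = c(10, NA))
  sr <- accumulateTracks(tr, g)
  expect_identical(sum(densityVolume(sr) > 0), 5L)
  expect_true(all(densityVolume(sr)[densityVolume(sr) > 0] == 1))
  # two segments crossing one voxel: vz 10 and 20 -> sum 30, density 2
  tr2 <- rbind(
    data.frame(track_id = 1L, frame = 1:2, z_mm = 0.05,
               x_mm = c(0.03, 0.05), y_mm = 0.05, vz_mm_s = c(10, NA)),
    data.frame(track_id = 2L, frame = 1:2, z_mm = 0.05,
               x_mm = c(0.05, 0.03), y_mm = 0.05, vz_mm_s = c(20, NA)))
  sr2 <- accumulateTracks(tr2, g)
  den <- densityVolume(sr2); vzs <- vzSumVolume(sr2)
  hot <- which(den == 2)
  expect_gt(length(hot), 0L)
  expect_true(all(vzs[hot] == 30))
  vm <- velocityMap(sr2, medianSize = 0)
  expect_true(all(vm[hot] == 15))
})

test_that("rasterized voxels equal a dense line-sampling oracle", {
  g <- imagingGrid(c(0, 0, 0), 0.01, c(20L, 20L, 20L))
  set.seed(12)
  for (i in 1:5) {
    p0 <- runif(3, 0.02, 0.17); p1 <- runif(3, 0.02, 0.17)
    tr <- data.frame(track_id = 1L, frame = 1:2,
                     z_mm = c(p0[1], p1[1]), x_mm = c(p0[2], p1[2]),
                     y_mm = c(p0[3], p1[3]), vz_mm_s = c(1, NA))
    sr <- accumulateTracks(tr, g)
    got <- which(densityVolume(sr) > 0)
    oracle <- rasterOracle(p0, p1, g, 0.01 / 4)
    want <- sort(unique(oracle[, 1] + (oracle[, 2] - 1) * 20 +
                          (oracle[, 3] - 1) * 400))
    expect_identical(got, as.integer(want))
  }
})

test_that("density is conserved and out-of-grid points are counted", {
  g <- imagingGrid(c(0, 0, 0), 0.01, c(8L, 8L, 8L))
  tr <- data.frame(track_id = 1L, frame = 1:2, z_mm = c(0.03, 0.2),
                   x_mm = 0.03, y_mm = 0.03, vz_mm_s = c(5, NA))
  sr <- accumulateTracks(tr, g)
  expect_gt(sr@clipped, 0L)
  expect_identical(sum(densityVolume(sr)),
                   sum(intensityVolume(sr)))
})

test_that("velocity map median filter matches the sorting oracle", {
  set.seed(13)
  a <- array(rnorm(7^3), c(7, 7, 7))
  expect_equal(medianFilter3(a, 3L), medianOracle(a, 3L))
  # uniform field unchanged; single outlier removed
  u <- array(5, c(5, 5, 5))
  expect_true(all(medianFilter3(u, 3L) == 5))
  u[3, 3, 3] <- 100
  expect_identical(medianFilter3(u, 3L)[3, 3, 3], 5)
  # subset evaluation agrees where evaluated
  sub <- array(FALSE, c(7, 7, 7)); sub[2:6, 2:6, 2:6] <- TRUE
  m <- medianFilter3(a, 3L, subset = sub)
  expect_equal(m[sub], medianOracle(a, 3L)[sub])
})

test_that("velocity map values stay within contributing segment range", {
  g <- imagingGrid(c(0, 0, 0), 0.01, c(12L, 12L, 12L))
  set.seed(14)
  tr <- do.call(rbind, lapply(1:6, function(id) {
    p <- runif(3, 0.02, 0.1)
    data.frame(track_id = id, frame = 1:2,
               z_mm = c(p[1], p[1] + 0.02), x_mm = p[2], y_mm = p[3],
               vz_mm_s = c(runif(1, -30, 30), NA))
  }))
  sr <- accumulateTracks(tr, g)
  vm <- velocityMap(sr, medianSize = 0)
  rng <- range(tr$vz_mm_s, na.rm = TRUE)
  expect_true(all(vm >= min(rng, 0) - 1e-9 & vm <= max(rng, 0) + 1e-9))
})

test_that("pass fusion averages overlaps and keeps single-pass voxels", {
  a <- array(c(4, 4, 0, 0), c(2, 2, 1))
  b <- array(c(2, 0, 2, 0), c(2, 2, 1))
  f <- fusePasses(a, b)
  expect_equal(as.vector(f), c(3, 4, 2, 0))
  expect_equal(fusePasses(a, a), a)              # idempotent
  expect_equal(fusePasses(a, b), fusePasses(b, a))  # commutative
  expect_error(fusePasses(a, array(0, c(2, 2, 2))), "match")
})

test_that("final smoothing is a unit-sum Gaussian of the stated sigma", {
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 1
  expect_identical(finalSmooth(a, 0), a)
  s <- finalSmooth(a, 0.8)
  expect_equal(sum(s), 1, tolerance = 1e-9)
  k <- exp(-(-3:3)^2 / (2 * 0.8^2)); k <- k / sum(k)
  expect_equal(s[6, 6, 6], k[4]^3, tolerance = 1e-9)
  expect_equal(s[5, 6, 6], k[3] * k[4]^2, tolerance = 1e-9)
})

test_that("directional split partitions the field and finds the 99.9% cap", {
  set.seed(15)
  vz <- array(rnorm(6^3) * 10, c(6, 6, 6))
  vz[sample(length(vz), 50)] <- 0
  sp <- directionalSplit(vz)
  expect_equal(sp$positive + sp$negative, vz)
  expect_true(all(sp$positive >= 0) && all(sp$negative <= 0))
  mag <- sort(abs(vz[vz != 0]))
  expect_identical(sp$saturationLimit, mag[ceiling(0.999 * length(mag))])
  # all-positive field has an empty negative volume
  sp2 <- directionalSplit(abs(vz))
  expect_true(all(sp2$negative == 0))
})

test_that("intensity projections equal the direct loop oracle", {
  set.seed(16)
  v <- array(rnorm(5^3), c(5, 5, 5))
  for (ax in 1:3) {
    got <- mip(v, c("z", "x", "y")[ax], "max")
    oracle <- apply(v, setdiff(1:3, ax), max)
    expect_equal(got, oracle)
    expect_true(all(mip(v, c("z", "x", "y")[ax], "min") <= got))
  }
  # constant volume -> constant image; slab restriction
  cst <- array(2, c(4, 4, 4))
  expect_true(all(mip(cst, "z") == 2))
  v2 <- v; v2[5, , ] <- 100
  expect_true(all(mip(v2, "z", slab = 1:4) < 100))
})

test_that("FWHM of a sampled Gaussian profile is 2.355 sigma", {
  x <- seq(-0.3, 0.3, by = 0.01)
  sig <- 0.05
  prof <- exp(-x^2 / (2 * sig^2))
  w <- vesselFwhm(prof, 0.01)
  expect_equal(w, 2.355 * sig * 1e3, tolerance = 0.02 * 2.355 * sig * 1e3)
  expect_equal(vesselFwhm(3.7 * prof, 0.01), w)   # scale invariant
  two <- exp(-(x - 0.12)^2 / (2 * 0.03^2)) + exp(-(x + 0.12)^2 / (2 * 0.03^2))
  expect_error(vesselFwhm(two, 0.01), "multiple peaks")
})

test_that("bifurcation separability returns the valley threshold", {
  x <- seq(0, 0.4, by = 0.01)
  prof <- exp(-(x - 0.12)^2 / (2 * 0.03^2)) + exp(-(x - 0.28)^2 / (2 * 0.03^2))
  bs <- bifurcationSeparation(prof, 0.01)
  expect_equal(bs$gapUm, 160, tolerance = 3)
  # oracle: smallest threshold that splits the supra-threshold support
  y <- spline(x, prof, n = length(x) * 10 - 9)$y
  seps <- vapply(seq(0.01, 0.99, by = 0.002), function(thr) {
    r <- rle(y > thr)
    sum(r$values) >= 2
  }, TRUE)
  thrOracle <- seq(0.01, 0.99, by = 0.002)[which(seps)[1]]
  expect_lt(abs(bs$threshold - thrOracle), 0.005)
  # merged peaks: no valley
  merged <- exp(-(x - 0.19)^2 / (2 * 0.05^2)) + exp(-(x - 0.21)^2 / (2 * 0.05^2))
  expect_error(bifurcationSeparation(merged, 0.01), "single peak")
})

test_that("bubble count series reproduces block means and box filter", {
  locs <- data.frame(frame = rep(1:1000, each = 10))
  bc <- bubbleCountSeries(locs, 1000L, blockSize = 200L, window = 5L)
  expect_true(all(bc$counts == 10))
  expect_equal(bc$blockMean, rep(10, 5))
  expect_equal(bc$smoothed, rep(10, 5))
  expect_true(all(bc$blockStd == 0))
  # moving average equals the direct windowed mean
  set.seed(17)
  locs2 <- data.frame(frame = sample(1:1000, 5000, TRUE))
  bc2 <- bubbleCountSeries(locs2, 1000L, 100L, 3L)
  oracle <- vapply(seq_along(bc2$blockMean), function(i)
    mean(bc2$blockMean[max(1, i - 1):min(length(bc2$blockMean), i + 1)]), 0)
  expect_equal(bc2$smoothed, oracle)
})

test_that("a steady-state synthetic scene holds its mean bubble count", {
  tree <- buildVesselTree(2, rootRadius = 0.08, rootPeakSpeed = 30,
                          lengthFactor = 15, seed = 18)
  target <- 86
  tb <- simulateBubbles(tree, duration = 2, frameRate = 250,
                        meanBubblesInView = target, seed = 18)
  bc <- bubbleCountSeries(tb$positions, tb$nFrames, blockSize = 100L)
  expect_lt(abs(mean(bc$blockMean) - target), 3 * sd(bc$blockMean) + 3)
})
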