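test_that("noise thresholding normalizes and zeroes the floor", {
  v <- array(c(0.005, 0.5, 1.0, rep(0.2, 24)), c(3, 3, 3))
  out <- noiseThreshold(v, 0.01)
  expect_equal(max(out), 1)
  expect_equal(sum(out == 0), 1L)     # only the 0.005 voxel dies
  # frac = 0: normalization only
  expect_equal(noiseThreshold(v, 0), v / max(v))
  # brute-force surviving count on random volumes
  set.seed(4)
  for (i in 1:5) {
    r <- array(runif(60), c(5, 4, 3))
    frac <- runif(1, 0.1, 0.6)
    expect_identical(sum(noiseThreshold(r, frac) > 0),
                     sum(r / max(r) >= frac))
  }
  expect_warning(noiseThreshold(array(0, c(2, 2, 2)), 0.1), "all-zero")
})

test_that("matched filter is the unit-sum PSF Gaussian convolution", {
  psf <- psfModel()
  sp <- lambdaMm() / 2
  # delta input reproduces the kernel up to boundary effects
  a <- array(0, c(15, 15, 15)); a[8, 8, 8] <- 1
  out <- matchFilter(a, psf, sp)
  expect_equal(sum(out), 1, tolerance = 1e-9)     # unit sum conserved
  sig <- c(psf$fwhmAxial, psf$fwhmLateral, psf$fwhmElevation) /
    (2 * sqrt(2 * log(2))) / sp
  expect_equal(out[8, 8, 8] / out[7, 8, 8], exp(0.5 / sig[1]^2),
               tolerance = 1e-3)
  # dense sliding-window oracle on a 9^3 volume
  set.seed(5)
  b <- array(runif(9^3), c(9, 9, 9))
  kern <- lapply(1:3, function(ax) {
    s <- sig[ax]
    k <- exp(-(seq(-max(1, ceiling(3 * s)), max(1, ceiling(3 * s))))^2 / (2 * s^2))
    k / sum(k)
  })
  expect_equal(matchFilter(b, psf, sp), denseConvOracle(b, kern),
               tolerance = 1e-10)
})

test_that("segmentation matches a flood-fill oracle on random masks", {
  set.seed(6)
  for (conn in c(6L, 18L, 26L)) {
    v <- array(runif(8 * 7 * 6), c(8, 7, 6))
    seg <- segmentBlobs(v, kStd = 0.5, connectivity = conn, minBlobVoxels = 1L)
    mask <- v > mean(v) + 0.5 * sd(v)
    oracle <- floodFillOracle(mask, conn)
    expect_identical(seg$nBlobs, max(oracle))
    # identical partition: labels agree up to renumbering
    tab <- table(seg$labels[mask], oracle[mask])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("segmentation thresholds behave at the extremes", {
  g <- imagingGrid(0, 0.1, c(21L, 21L, 11L))
  a <- array(0, c(21, 21, 11))
  mk <- function(c0, amp) {
    for (z in 1:21) for (x in 1:21) for (y in 1:11)
      a[z, x, y] <<- a[z, x, y] +
        amp * exp(-sum((c(z, x, y) - c0)^2 / (2 * 1.2^2)))
  }
  mk(c(6, 6, 6), 1); mk(c(16, 16, 6), 1)   # separation >> 6 sigma
  seg <- segmentBlobs(a, kStd = 2, minBlobVoxels = 2L)
  expect_identical(seg$nBlobs, 2L)
  expect_identical(segmentBlobs(a, kStd = 1e6)$nBlobs, 0L)
})

test_that("weighted centroid is the definitional intensity-weighted mean", {
  g <- imagingGrid(c(0, 0, 0), c(1, 1, 1), c(4L, 4L, 4L))
  # voxels at z-index 1 and 2, weights 1 and 3 -> z = 0.75 in physical mm
  p <- weightedCentroid(rbind(c(1, 1, 1), c(2, 1, 1)), c(1, 3), g)
  expect_equal(unname(p), c(0.75, 0, 0))
  # symmetric weights give the geometric center
  vox <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  expect_equal(unname(weightedCentroid(vox, rep(2, 27), g)), c(1, 1, 1))
  # random blobs vs direct summation
  set.seed(7)
  for (i in 1:10) {
    vx <- cbind(sample(4, 5, TRUE), sample(4, 5, TRUE), sample(4, 5, TRUE))
    w <- runif(5)
    oracle <- colSums(sweep(vx - 1, 1, w, "*")) / sum(w)
    expect_equal(unname(weightedCentroid(vx, w, g)), unname(oracle))
  }
  expect_null(weightedCentroid(rbind(c(1, 1, 1)), 0, g))
})

test_that("a single synthetic bubble yields one sub-voxel localization", {
  g <- imagingGrid(c(0.5, -1, -1), lambdaMm() / 2, c(20L, 20L, 20L))
  truth <- oneBubbleTruth(z = 1.23, x = -0.117, y = -0.256)
  vs <- renderBmode(truth, psfModel(), NULL, g)
  locs <- localizePass(vs, localizeConfig(segmentKStd = 2), "low")
  expect_identical(nrow(locs), 1L)
  err <- abs(c(locs$z_mm - 1.23, locs$x_mm + 0.117, locs$y_mm + 0.256))
  expect_true(all(err < lambdaMm() / 4))   # within half a lambda/2 voxel
  # empty frames produce an empty list
  empty <- volumeSequence(array(0, c(4, 4, 4, 2)),
                          imagingGrid(0, 0.1, c(4L, 4L, 4L)), 500)
  expect_identical(nrow(suppressWarnings(
    localizePass(empty, localizeConfig(), "low"))), 0L)
})

test_that("two well-separated bubbles localize independently", {
  g <- imagingGrid(c(0.5, -1.5, -1.5), lambdaMm() / 2, c(20L, 32L, 32L))
  pos <- rbind(
    data.frame(frame = 1L, id = 1L, z_mm = 1.1, x_mm = -0.9, y_mm = -0.8,
               amplitude = 1, speed_mm_s = 0),
    data.frame(frame = 1L, id = 2L, z_mm = 1.4, x_mm = 0.6, y_mm = 0.7,
               amplitude = 2, speed_mm_s = 0))
  vs <- renderBmode(truthFrom(pos, nFrames = 1L), psfModel(), NULL, g)
  locs <- localizePass(vs, localizeConfig(segmentKStd = 1.5), "low")
  expect_identical(nrow(locs), 2L)
  for (i in 1:2) {
    d <- sqrt((locs$z_mm - pos$z_mm[i])^2 + (locs$x_mm - pos$x_mm[i])^2 +
                (locs$y_mm - pos$y_mm[i])^2)
    expect_lt(min(d), lambdaMm() / 4)
  }
})

test_that("dual-pass thresholds trade dim sensitivity for separability", {
  # a crowded frame (realistic backdrop of moderate bubbles) plus one dim
  # isolated bubble and one closely spaced bright pair: the low threshold
  # keeps the dim bubble but merges the pair, the high threshold discards
  # the dim bubble but resolves the pair
  g <- imagingGrid(c(0.5, -1.5, -1.5), lambdaMm() / 2, c(20L, 32L, 32L))
  set.seed(33)
  nbg <- 60L
  sep <- 0.6
  bg <- data.frame(frame = 1L, id = 10L + seq_len(nbg),
                   z_mm = runif(nbg, 0.8, 2.2),
                   x_mm = runif(nbg, -1.4, -0.2),
                   y_mm = runif(nbg, -1.4, -0.2),
                   amplitude = runif(nbg, 3, 8), speed_mm_s = 0)
  pos <- rbind(
    data.frame(frame = 1L, id = 1L, z_mm = 1.1, x_mm = 0.9, y_mm = -1.0,
               amplitude = 2.5, speed_mm_s = 0),
    data.frame(frame = 1L, id = 2L, z_mm = 1.4, x_mm = 0.5 - sep / 2,
               y_mm = 0.6, amplitude = 10, speed_mm_s = 0),
    data.frame(frame = 1L, id = 3L, z_mm = 1.4, x_mm = 0.5 + sep / 2,
               y_mm = 0.6, amplitude = 10, speed_mm_s = 0),
    bg)
  vs <- renderBmode(truthFrom(pos, nFrames = 1L), psfModel(), NULL, g)
  locs <- dualPassLocalize(vs, localizeConfig(0.03, 1.0),
                           localizeConfig(0.03, 3.5))
  low <- locs[locs$pass == "low", ]
  high <- locs[locs$pass == "high", ]
  nearDim <- function(L) sum(sqrt((L$z_mm - 1.1)^2 + (L$x_mm - 0.9)^2 +
                                    (L$y_mm + 1)^2) < 0.2)
  expect_identical(nearDim(low), 1L)   # low pass finds the dim bubble
  expect_identical(nearDim(high), 0L)  # high pass discards it
  nearPair <- function(L) sum(sqrt((L$z_mm - 1.4)^2 + (L$y_mm - 0.6)^2) < 0.45 &
                                abs(L$x_mm - 0.5) < 0.6)
  expect_identical(nearPair(low), 1L)  # merged under the low threshold
  expect_identical(nearPair(high), 2L) # resolved under the high threshold
  # identical configs give identical sets
  same <- dualPassLocalize(vs, localizeConfig(0.03, 2), localizeConfig(0.03, 2))
  expect_equal(same[same$pass == "low", -1], same[same$pass == "high", -1],
               ignore_attr = TRUE)
})

test_that("raising the threshold never adds blobs for isolated spots", {
  # monotone blob counts hold for well-separated unimodal spots; for
  # overlapping spots a higher threshold can legitimately split one blob
  # into two — that splitting is the whole point of the high pass
  a <- array(0, c(12, 24, 12))
  ctrs <- rbind(c(6, 4, 6), c(6, 12, 6), c(6, 20, 6))
  amps <- c(0.5, 1, 2)
  for (i in 1:3)
    for (z in 1:12) for (x in 1:24) for (y in 1:12)
      a[z, x, y] <- a[z, x, y] +
        amps[i] * exp(-sum((c(z, x, y) - ctrs[i, ])^2) / (2 * 1.1^2))
  counts <- vapply(c(0.5, 1.5, 3, 6, 1e6),
                   function(k) segmentBlobs(a, k, minBlobVoxels = 1L)$nBlobs, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[5], 0L)
})

test_that("frames are processed independently", {
  g <- imagingGrid(c(0.5, -1, -1), lambdaMm() / 2, c(16L, 16L, 16L))
  set.seed(9)
  pos <- do.call(rbind, lapply(1:4, function(t)
    data.frame(frame = t, id = t, z_mm = runif(1, 0.8, 1.5),
               x_mm = runif(1, -0.7, 0.3), y_mm = runif(1, -0.7, 0.3),
               amplitude = 1, speed_mm_s = 0)))
  vs <- renderBmode(truthFrom(pos, nFrames = 4L), psfModel(), NULL, g)
  locs <- localizePass(vs, localizeConfig(segmentKStd = 2), "low")
  # permute the frame order: per-frame results permute identically
  perm <- c(3L, 1L, 4L, 2L)
  aperm_a <- frameArray(vs)[, , , perm]
  vsp <- volumeSequence(aperm_a, g, 500)
  locsp <- localizePass(vsp, localizeConfig(segmentKStd = 2), "low")
  for (t in 1:4) {
    a <- locs[locs$frame == perm[t], c("z_mm", "x_mm", "y_mm", "intensity")]
    b <- locsp[locsp$frame == t, c("z_mm", "x_mm", "y_mm", "intensity")]
    expect_equal(a, b, ignore_attr = TRUE)
  }
})
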