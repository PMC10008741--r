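test_that("vessel tree follows Murray's law and conserves flow", {
  tree <- buildVesselTree(2, rootRadius = 0.1, rootPeakSpeed = 40, seed = 1)
  expect_length(tree, 7L)                       # 1 + 2 + 4
  expect_length(buildVesselTree(0, seed = 1), 1L)
  for (s in tree) {
    if (length(s$children) == 0L) next
    kids <- tree[s$children]
    for (k in kids) {
      expect_equal(k$radius, s$radius * 2^(-1 / 3))
      expect_equal(k$peakSpeed, s$peakSpeed * 2^(-1 / 3))
    }
    # sum of child cross-section x mean speed equals the parent's
    childFlow <- sum(vapply(kids, function(k) pi * k$radius^2 * k$peakSpeed / 2, 0))
    expect_equal(childFlow, pi * s$radius^2 * s$peakSpeed / 2)
    # children start where the parent ends
    for (k in kids) expect_equal(k$start, s$end)
  }
})

test_that("vessel tree generation is deterministic under a fixed seed", {
  expect_identical(buildVesselTree(3, seed = 42), buildVesselTree(3, seed = 42))
  expect_false(identical(buildVesselTree(3, seed = 42),
                         buildVesselTree(3, seed = 43)))
})

test_that("bubble kinematics follow the Poiseuille advance rule", {
  # stationary tree: zero peak speed would stall forever, so test the
  # centerline displacement arithmetic instead: v * dt per frame
  tree <- buildVesselTree(0, rootRadius = 0.05, rootPeakSpeed = 20,
                          rootStart = c(1, -1, 0), rootDirection = c(0, 1, 0),
                          lengthFactor = 60, seed = 2)
  tb <- simulateBubbles(tree, duration = 0.5, frameRate = 500,
                        meanBubblesInView = 3, radialMode = "centerline",
                        seed = 2)
  p <- tb$positions
  p <- p[order(p$id, p$frame), ]
  steps <- unlist(lapply(split(p, p$id), function(d) {
    if (nrow(d) < 2L) return(numeric(0))
    ok <- diff(d$frame) == 1L
    sqrt(diff(d$z_mm)^2 + diff(d$x_mm)^2 + diff(d$y_mm)^2)[ok]
  }))
  expect_equal(unname(steps), rep(20 / 500, length(steps)), tolerance = 1e-9)
  # centerline bubbles move at the peak speed
  expect_true(all(abs(p$speed_mm_s - 20) < 1e-9))
})

test_that("flux-mode bubbles stay inside their vessel radius", {
  tree <- buildVesselTree(1, rootRadius = 0.1, rootPeakSpeed = 30,
                          rootStart = c(0, 0, 0), rootDirection = c(0, 1, 0),
                          lengthFactor = 20, seed = 5)
  tb <- simulateBubbles(tree, duration = 0.4, frameRate = 250,
                        meanBubblesInView = 10, seed = 5)
  p <- tb$positions
  # distance from every position to the nearest segment axis <= its radius
  distToSeg <- function(q, s) {
    t <- sum((q - s$start) * s$direction)
    t <- min(max(t, 0), s$length)
    sqrt(sum((q - (s$start + t * s$direction))^2))
  }
  for (i in sample(nrow(p), min(200, nrow(p)))) {
    q <- as.numeric(p[i, c("z_mm", "x_mm", "y_mm")])
    dmin <- min(vapply(tree, function(s) distToSeg(q, s) - s$radius, 0))
    expect_lt(dmin, 1e-9)
  }
})

test_that("steady-state in-view count matches the Poisson calibration", {
  tree <- buildVesselTree(2, rootRadius = 0.08, rootPeakSpeed = 30,
                          lengthFactor = 15, seed = 3)
  target <- 15
  tb <- simulateBubbles(tree, duration = 2, frameRate = 100,
                        meanBubblesInView = target, seed = 4)
  counts <- tabulate(tb$positions$frame, tb$nFrames)
  expect_lt(abs(mean(counts) - target), 3 * sqrt(target))
  # determinism
  tb2 <- simulateBubbles(tree, duration = 2, frameRate = 100,
                         meanBubblesInView = target, seed = 4)
  expect_identical(tb$positions, tb2$positions)
})

test_that("B-mode rendering places the PSF at the true position", {
  g <- imagingGrid(c(0.5, -1, -1), lambdaMm() / 2, c(20L, 20L, 20L))
  truth <- oneBubbleTruth(z = 1.23, x = -0.117, y = -0.256)
  vs <- renderBmode(truth, psfModel(), NULL, g)
  a <- frameArray(vs)[, , , 1]
  pk <- arrayInd(which.max(a), dim(a))
  pos <- voxelToPhys(g, as.numeric(pk))
  expect_true(all(abs(pos - c(1.23, -0.117, -0.256)) <= gridSpacing(g)))
  # center value of the kernel equals the amplitude at the exact position
  truthOn <- oneBubbleTruth(z = voxelToPhys(g, c(10, 10, 10))[1],
                            x = voxelToPhys(g, c(10, 10, 10))[2],
                            y = voxelToPhys(g, c(10, 10, 10))[3], amp = 2.5)
  a2 <- frameArray(renderBmode(truthOn, psfModel(), NULL, g))[, , , 1]
  expect_equal(a2[10, 10, 10], 2.5, tolerance = 1e-12)
})

test_that("rendering is linear in bubble amplitude before noise", {
  g <- imagingGrid(c(0.5, -1, -1), lambdaMm() / 2, c(16L, 16L, 16L))
  t1 <- oneBubbleTruth(z = 1.0, x = -0.3, y = -0.2, amp = 1)
  t3 <- oneBubbleTruth(z = 1.0, x = -0.3, y = -0.2, amp = 3)
  a1 <- frameArray(renderBmode(t1, psfModel(), NULL, g))
  a3 <- frameArray(renderBmode(t3, psfModel(), NULL, g))
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("zero bubbles with purely static clutter gives identical frames", {
  g <- imagingGrid(0, 0.1, c(8L, 8L, 8L))
  truth <- truthFrom(data.frame(frame = integer(0), id = integer(0),
                                z_mm = numeric(0), x_mm = numeric(0),
                                y_mm = numeric(0), amplitude = numeric(0),
                                speed_mm_s = numeric(0)), 500, 5L)
  noise <- sceneNoiseModel(clutterTemporalModes = 0, noiseStd = 0)
  a <- frameArray(renderBmode(truth, psfModel(), noise, g, seed = 8))
  for (t in 2:5) expect_identical(a[, , , t], a[, , , 1])
})

test_that("clutter occupies exactly the advertised temporal rank", {
  g <- imagingGrid(0, 0.1, c(10L, 12L, 8L))
  truth <- truthFrom(data.frame(frame = integer(0), id = integer(0),
                                z_mm = numeric(0), x_mm = numeric(0),
                                y_mm = numeric(0), amplitude = numeric(0),
                                speed_mm_s = numeric(0)), 500, 60L)
  noise <- sceneNoiseModel(clutterTemporalModes = 8, clutterChunkFrames = 60,
                           noiseStd = 0)
  a <- frameArray(renderBmode(truth, psfModel(), noise, g, seed = 8))
  sv <- svd(casorati(a), nu = 0, nv = 0)$d
  expect_gt(sv[9], 1)           # static + 8 modes all strong
  expect_lt(sv[10] / sv[9], 1e-8)  # hard rank cliff at 9
})

test_that("simulated RF puts the pulse at the geometric delay", {
  probe <- probeGeometry(8, 8, pitch = 0.3)
  fs <- 4 * 7.81e6
  z <- 5
  rf <- simulateRf(c(z, 0, 0), probe = probe, angles = c(0, 0),
                   sampleRate = fs, nSamples = 600)
  # center element column: envelope peak near t = (z + |r - e|)/c
  elem <- elementPositions(probe)
  eC <- which.min(rowSums(elem[, 2:3]^2))
  tr <- rf$rf[, eC, 1]
  tPk <- (which.max(abs(tr)) - 1) / fs
  tGeom <- (z + sqrt(sum((c(z, 0, 0) - elem[eC, ])^2))) * 1e-3 / 1540
  expect_lt(abs(tPk - tGeom), 1.5 / 7.81e6)
  # linearity: two scatterers = sum of singles
  rf2 <- simulateRf(rbind(c(5, 0.4, 0), c(6, -0.3, 0.2)),
                    amplitudes = c(1, 2), probe = probe,
                    angles = c(0, 0), sampleRate = fs, nSamples = 600)
  rfa <- simulateRf(c(5, 0.4, 0), probe = probe, angles = c(0, 0),
                    sampleRate = fs, nSamples = 600)
  rfb <- simulateRf(c(6, -0.3, 0.2), probe = probe, angles = c(0, 0),
                    sampleRate = fs, nSamples = 600)
  expect_equal(rf2$rf, rfa$rf + 2 * rfb$rf, tolerance = 1e-12)
})

test_that("off-axis element delays match a brute-force geometry oracle", {
  probe <- probeGeometry(4, 4, pitch = 0.3)
  elem <- elementPositions(probe)
  fs <- 50e6
  sc <- c(4.2, 0.7, -0.5)
  ang <- c(3, -2)
  rf <- simulateRf(sc, probe = probe, angles = ang, sampleRate = fs,
                   nSamples = 800)
  sx <- sin(ang[1] * pi / 180); sy <- sin(ang[2] * pi / 180)
  sz <- sqrt(1 - sx^2 - sy^2)
  for (e in sample(nrow(elem), 6)) {
    tauOracle <- ((sc[1] * sz + sc[2] * sx + sc[3] * sy) +
                    sqrt(sum((sc - elem[e, ])^2))) * 1e-3 / 1540
    tr <- rf$rf[, e, 1]
    tPk <- (which.max(abs(tr)) - 1) / fs
    expect_lt(abs(tPk - tauOracle), 1.5 / 7.81e6)
  }
})
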