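# Shared synthetic fixtures, built in code. Expensive ones are cached for
# the session so several test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

lambdaMm <- function() wavelength(7.81e6) / 1e3

sceneGrid <- function() imagingGrid(c(0.3, -2.2, -2.2), lambdaMm() / 2,
                                    c(32L, 48L, 48L))

# single bright bubble at a known sub-voxel position, clean render
oneBubbleTruth <- function(z = 1.23, x = 0.117, y = -0.256, amp = 1,
                           frames = 1L) {
  structure(list(
    positions = data.frame(frame = seq_len(frames), id = 1L, z_mm = z,
                           x_mm = x, y_mm = y, amplitude = amp,
                           speed_mm_s = 0),
    frameRate = 500, nFrames = frames), class = "BubbleTruth")
}

truthFrom <- function(positions, frameRate = 500,
                      nFrames = max(positions$frame)) {
  structure(list(positions = positions, frameRate = frameRate,
                 nFrames = as.integer(nFrames)), class = "BubbleTruth")
}

# the packaged acceptance scene: default pipeline on a fixed seed
acceptanceRun <- function(seed = 1L) {
  cached(paste0("acceptance_run_", seed), {
    out <- file.path(tempdir(), paste0("ulm3d_acc_", seed))
    m <- suppressMessages(suppressWarnings(
      runPipeline(outDir = out, seed = seed)))
    list(manifest = m, dir = out,
         truth = read.csv(file.path(out, "truth.csv")),
         locs = read.csv(file.path(out, "localizations.csv")))
  })
}

# match truth bubbles to localizations; returns per-row hit flags, errors,
# nearest-neighbour distances and in-grid flags
matchTruth <- function(truth, locs, grid, gate = 0.15) {
  truth <- truth[order(truth$frame, truth$id), ]
  lo <- gridOrigin(grid)
  hi <- lo + (gridDim(grid) - 1) * gridSpacing(grid)
  inGrid <- truth$z_mm >= lo[1] & truth$z_mm <= hi[1] &
    truth$x_mm >= lo[2] & truth$x_mm <= hi[2] &
    truth$y_mm >= lo[3] & truth$y_mm <= hi[3]
  nn <- unlist(lapply(split(seq_len(nrow(truth)), truth$frame), function(ix) {
    if (length(ix) == 1L) return(Inf)
    P <- as.matrix(truth[ix, c("z_mm", "x_mm", "y_mm")])
    D <- as.matrix(dist(P)); diag(D) <- Inf
    apply(D, 1, min)
  }))
  hits <- rep(FALSE, nrow(truth))
  errs <- matrix(NA_real_, nrow(truth), 3)
  for (fr in unique(truth$frame)) {
    ti <- which(truth$frame == fr)
    Lf <- locs[locs$frame == fr, ]
    if (!nrow(Lf)) next
    for (i in ti) {
      d <- sqrt((Lf$z_mm - truth$z_mm[i])^2 + (Lf$x_mm - truth$x_mm[i])^2 +
                  (Lf$y_mm - truth$y_mm[i])^2)
      j <- which.min(d)
      if (d[j] < gate) {
        hits[i] <- TRUE
        errs[i, ] <- c(Lf$z_mm[j] - truth$z_mm[i],
                       Lf$x_mm[j] - truth$x_mm[i],
                       Lf$y_mm[j] - truth$y_mm[i])
      }
    }
  }
  list(truth = truth, hits = hits, errs = errs, nn = nn, inGrid = inGrid)
}

# noise-free single-vessel centerline scene (detection rate ~1) for the
# tracking speed check
speedSceneTracks <- function(seed = 9L) {
  cached(paste0("speed_scene_", seed), {
    grid <- sceneGrid()
    tree <- buildVesselTree(0, rootRadius = 0.05, rootPeakSpeed = 20,
                            rootStart = c(1.5, -1.8, 0),
                            rootDirection = c(0.1, 1, 0.05),
                            lengthFactor = 70, seed = seed)
    truth <- simulateBubbles(tree, duration = 1, frameRate = 500,
                             meanBubblesInView = 6,
                             radialMode = "centerline", seed = seed)
    vs <- renderBmode(truth, psfModel(), NULL, grid)
    locs <- localizePass(vs, localizeConfig(0.03, 1.5), "low")
    trackLocalizations(locs, 500, trackConfig())
  })
}

# two parallel 60 um separated vessels, clean render: the super-resolution
# phantom (criterion: resolved at lambda/20, unresolved at lambda/2)
twoVesselPhantom <- function(seed = 11L, sepMm = 0.060) {
  cached(paste0("two_vessel_", seed), {
    lam <- lambdaMm()
    grid <- imagingGrid(c(0.5, -1.8, -0.6), lam / 2, c(16L, 40L, 16L))
    mkv <- function(y0, s) {
      tree <- buildVesselTree(0, rootRadius = 0.005, rootPeakSpeed = 20,
                              rootStart = c(1.2, -1.5, y0),
                              rootDirection = c(0, 1, 0),
                              lengthFactor = 600, seed = s)
      simulateBubbles(tree, duration = 2, frameRate = 500,
                      meanBubblesInView = 2, radialMode = "centerline",
                      seed = s)
    }
    t1 <- mkv(-sepMm / 2, seed)
    t2 <- mkv(sepMm / 2, seed + 1L)
    p2 <- t2$positions
    p2$id <- p2$id + 10000L
    truth <- truthFrom(rbind(t1$positions, p2), 500, 1000L)
    vs <- renderBmode(truth, psfModel(), NULL, grid)
    locs <- dualPassLocalize(vs, localizeConfig(0.03, 1.5),
                             localizeConfig(0.03, 3.5))
    tracks <- trackLocalizations(locs[locs$pass == "low", ], 500,
                                 trackConfig())
    list(grid = grid, locs = locs, tracks = tracks)
  })
}

# random point field hard-low-passed at a known spectral cutoff
bandLimitedPhantom <- function(n = 96L, spacing = lambdaMm() / 20,
                               cutFrac = 0.6, seed = 3L) {
  set.seed(seed)
  v <- array(0, c(n, n, n))
  idx <- sample(length(v), 4000L)
  v[idx] <- runif(4000L, 0.5, 1)
  F <- fft(v)
  fr <- lapply(1:3, function(ax) {
    k <- 0:(n - 1L); k[k > n / 2] <- k[k > n / 2] - n
    k / (n * spacing * 1e3)
  })
  rad <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+"))
  subNyq <- 1 / (4 * spacing * 1e3)
  fc <- cutFrac * subNyq
  F[rad > fc] <- 0
  vb <- Re(fft(F, inverse = TRUE)) / length(F)
  vb <- vb + rnorm(length(vb), 0, sd(vb) * 0.05)
  list(volume = vb, cutoff = fc, spacing = spacing)
}
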