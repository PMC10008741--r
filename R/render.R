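#' Build a super-resolution rendering grid over tracks
#'
#' Convenience constructor for the fine (default lambda/20 = 9.86 um)
#' rendering grid covering a set of tracks with a margin.
#'
#' @param tracks track data.frame (smoothed positions used when present).
#' @param spacing voxel size in mm (default lambda/20 at 7.81 MHz).
#' @param margin margin around the track bounding box, mm.
#' @param roi optional region of interest: list with `lo` and `hi`
#'   (z, x, y) mm corners overriding the track bounding box; track voxels
#'   outside it are clipped (and counted) at accumulation time.
#' @return an [ImagingGrid-class].
#' @export
superResGrid <- function(tracks, spacing = wavelength(7.81e6) / 20 / 1e3,
                         margin = 0.05, roi = NULL) {
  if (!is.null(roi)) {
    lo <- as.numeric(roi$lo)
    hi <- as.numeric(roi$hi)
  } else {
    p <- trackPositions(tracks)
    lo <- apply(p, 2, min) - margin
    hi <- apply(p, 2, max) + margin
  }
  dim <- pmax(1L, ceiling((hi - lo) / spacing) + 1L)
  # even lateral/elevation counts so the FSC checkerboard split is exact
  dim[2:3] <- dim[2:3] + dim[2:3] %% 2L
  imagingGrid(lo, spacing, dim)
}

trackPositions <- function(tracks) {
  cols <- if ("z_sm" %in% names(tracks)) c("z_sm", "x_sm", "y_sm")
          else c("z_mm", "x_mm", "y_mm")
  as.matrix(tracks[, cols])
}

#' Accumulate tracks onto a super-resolution grid
#'
#' Every track segment (pair of consecutive smoothed positions) is
#' rasterized as the 3-D digital line of voxels between its endpoints
#' (supersampled at a quarter voxel and uniqued); each visited voxel gets
#' `intensity += 1`, `density += 1` and `vzSum += ` the segment's signed
#' axial velocity. Points outside the grid are clipped and counted.
#'
#' @param tracks data.frame from [trackLocalizations()] (needs `vz_mm_s`;
#'   missing velocities count as 0).
#' @param grid the rendering [ImagingGrid-class].
#' @return a [SuperResVolume-class].
#' @export
accumulateTracks <- function(tracks, grid) {
  d <- gridDim(grid)
  intensity <- array(0, d)
  vzSum <- array(0, d)
  clipped <- 0L
  if (nrow(tracks)) {
    p <- trackPositions(tracks)
    vz <- if ("vz_mm_s" %in% names(tracks)) tracks$vz_mm_s else
      rep(0, nrow(tracks))
    step <- min(gridSpacing(grid)) / 4
    ids <- tracks$track_id
    for (r in seq_len(nrow(tracks) - 1L)) {
      if (ids[r + 1L] != ids[r]) next
      vox <- rasterizeSegment(p[r, ], p[r + 1L, ], grid, step)
      inb <- vox[, 1] >= 1L & vox[, 1] <= d[1] &
             vox[, 2] >= 1L & vox[, 2] <= d[2] &
             vox[, 3] >= 1L & vox[, 3] <= d[3]
      clipped <- clipped + sum(!inb)
      if (!any(inb)) next
      vox <- vox[inb, , drop = FALSE]
      sv <- if (is.na(vz[r])) 0 else vz[r]
      intensity[vox] <- intensity[vox] + 1
      vzSum[vox] <- vzSum[vox] + sv
    }
  }
  new("SuperResVolume", grid = grid, intensity = intensity,
      density = intensity, vzSum = vzSum, clipped = clipped)
}

rasterizeSegment <- function(p0, p1, grid, step) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  vox <- round(physToVoxel(grid, pts))
  unique(vox)
}

#' Mean axial-velocity map
#'
#' Divides the accumulated signed axial-velocity volume by the density map
#' (voxels never visited stay 0), then applies a 3-D median filter to
#' remove residual noisy tracks. The median is evaluated only where the
#' neighborhood contains signal; elsewhere it is zero by construction.
#'
#' @param vol a [SuperResVolume-class].
#' @param medianSize odd kernel edge length (default 3); 0 skips the
#'   filter.
#' @return 3-D array of mean axial velocities, mm/s.
#' @export
velocityMap <- function(vol, medianSize = 3L) {
  den <- densityVolume(vol)
  vz <- vzSumVolume(vol)
  out <- array(0, dim(vz))
  nz <- den > 0
  out[nz] <- vz[nz] / den[nz]
  if (medianSize >= 3L)
    out <- medianFilter3(out, medianSize,
                         subset = dilateNonzero3(out, medianSize))
  out
}

#' Fuse the two localization passes
#'
#' Voxelwise combination of two rendered volumes: where both are non-zero
#' the mean is taken, where only one is non-zero that value is kept. This
#' prevents vessels detected by both passes from rendering twice as bright
#' as vessels seen by only one. Commutative and idempotent.
#'
#' @param low,high 3-D arrays on the same grid.
#' @return fused array.
#' @export
fusePasses <- function(low, high) {
  if (!identical(dim(low), dim(high))) stop("grids do not match")
  both <- low != 0 & high != 0
  out <- low + high
  out[both] <- out[both] / 2
  out
}

#' Final cosmetic Gaussian smoothing
#'
#' Isotropic Gaussian blur of the rendered volume, sigma in (rendering)
#' voxels, default 0.8. `sigma = 0` is the identity.
#'
#' @param volume 3-D array.
#' @param sigma standard deviation in voxels.
#' @return smoothed array.
#' @export
finalSmooth <- function(volume, sigma = 0.8) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  gaussSmooth3(volume, rep(sigma, 3))
}

#' Split a velocity volume by flow direction
#'
#' Separates positive (downward) and negative (upward) axial flow and
#' computes the color-map saturation limit as the 99.9th percentile of the
#' velocity magnitudes over non-zero voxels (the smallest magnitude that
#' covers 99.9% of detected velocities).
#'
#' @param vz 3-D array of signed axial velocities.
#' @param percentile coverage fraction (default 0.999).
#' @return list with `positive`, `negative` (arrays; `positive + negative`
#'   reconstructs `vz`) and `saturationLimit` (mm/s).
#' @export
directionalSplit <- function(vz, percentile = 0.999) {
  pos <- vz * (vz > 0)
  neg <- vz * (vz < 0)
  mag <- sort(abs(vz[vz != 0]))
  sat <- if (length(mag)) mag[max(1L, ceiling(percentile * length(mag)))]
         else 0
  list(positive = pos, negative = neg, saturationLimit = sat)
}

#' Intensity projection along an axis
#'
#' Maximum (or minimum) intensity projection of a volume along the axial,
#' lateral or elevation axis, optionally restricted to a slab of voxel
#' indices (sectional MIPs).
#'
#' @param volume 3-D array (z, x, y).
#' @param axis `"z"`, `"x"` or `"y"`.
#' @param type `"max"` (default) or `"min"`.
#' @param slab optional integer range of voxel indices along `axis`.
#' @return 2-D matrix of per-pixel extremes.
#' @export
mip <- function(volume, axis = c("z", "x", "y"), type = c("max", "min"),
                slab = NULL) {
  axis <- match.arg(axis)
  type <- match.arg(type)
  ax <- match(axis, c("z", "x", "y"))
  if (!is.null(slab)) volume <- indexAxis3(volume, ax, slab)
  f <- if (type == "max") max else min
  apply(volume, setdiff(1:3, ax), f)
}

#' Vessel width by full width at half maximum
#'
#' The 1-D cross-section profile is cubic-spline interpolated (default 10x
#' denser) and the width between the two half-maximum crossings around the
#' single dominant peak is returned. Profiles with more than one peak
#' above half maximum, or without two crossings, are an error.
#'
#' @param profile 1-D intensity samples across the vessel.
#' @param spacing sample spacing in mm.
#' @param upsample spline upsampling factor (default 10).
#' @return width in micrometres.
#' @examples
#' x <- seq(-0.3, 0.3, by = 0.01)
#' vesselFwhm(exp(-x^2 / (2 * 0.05^2)), 0.01)  # ~ 2.355 * 50 um
#' @export
vesselFwhm <- function(profile, spacing, upsample = 10L) {
  n <- length(profile)
  if (n < 4L) stop("profile too short")
  sp <- stats::spline(x = (seq_len(n) - 1) * spacing, y = profile,
                      n = (n - 1L) * upsample + 1L)
  y <- sp$y; x <- sp$x
  half <- max(y) / 2
  pk <- localMaxima(y)
  pk <- pk[y[pk] > half]
  if (length(pk) > 1L) stop("profile has multiple peaks above half maximum")
  if (length(pk) == 0L) pk <- which.max(y)
  left <- which(y[seq_len(pk)] < half)
  right <- which(y[pk:length(y)] < half) + pk - 1L
  if (!length(left) || !length(right))
    stop("no half-maximum crossing on both sides; width undefined")
  l <- max(left); r <- min(right)
  xl <- x[l] + (half - y[l]) / (y[l + 1L] - y[l]) * (x[l + 1L] - x[l])
  xr <- x[r - 1L] + (half - y[r - 1L]) / (y[r] - y[r - 1L]) * (x[r] - x[r - 1L])
  (xr - xl) * 1e3
}

localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

#' Separability of a bifurcation
#'
#' For a two-peaked cross-section profile, returns the valley intensity —
#' the minimum threshold above which the two peaks form disjoint
#' supra-threshold components — and the peak-to-peak distance. A profile
#' whose peaks have merged (a single local maximum) is an error.
#'
#' @param profile 1-D intensity samples across the bifurcation.
#' @param spacing sample spacing in mm.
#' @param upsample spline upsampling factor (default 10).
#' @param minPeakFrac candidate peaks must reach this fraction of the
#'   profile maximum (default 0.25); guards against spline-interpolation
#'   ripples being mistaken for vessels.
#' @return list with `threshold` (valley intensity), `gapUm`
#'   (peak-to-peak distance in um) and `peakPositionsUm`.
#' @export
bifurcationSeparation <- function(profile, spacing, upsample = 10L,
                                  minPeakFrac = 0.25) {
  n <- length(profile)
  if (n < 4L) stop("profile too short")
  sp <- stats::spline(x = (seq_len(n) - 1) * spacing, y = profile,
                      n = (n - 1L) * upsample + 1L)
  y <- sp$y; x <- sp$x
  pk <- localMaxima(y)
  pk <- pk[y[pk] >= minPeakFrac * max(y)]
  if (length(pk) < 2L)
    stop("profile has a single peak; vessels are not separable")
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  pk <- sort(pk)
  valley <- min(y[pk[1]:pk[2]])
  if (valley >= min(y[pk]))
    stop("peaks are merged; no separating threshold exists")
  list(threshold = valley,
       gapUm = (x[pk[2]] - x[pk[1]]) * 1e3,
       peakPositionsUm = x[pk] * 1e3)
}

#' Bubble-count time series
#'
#' Localizations per volume, block means/standard deviations over
#' `blockSize`-frame blocks, and a centered moving (box) average of the
#' block means (partial windows at the edges).
#'
#' @param locs localization data.frame with a `frame` column.
#' @param nFrames total number of frames.
#' @param blockSize frames per block (default 200, i.e. 0.4 s at 500 vps).
#' @param window odd moving-average window in blocks (default 5).
#' @return list with `counts` (per frame), `blockMean`, `blockStd`,
#'   `smoothed` (box-filtered block means).
#' @export
bubbleCountSeries <- function(locs, nFrames, blockSize = 200L, window = 5L) {
  if (window %% 2L == 0L) stop("window must be odd")
  counts <- tabulate(locs$frame, nbins = nFrames)
  nBlocks <- nFrames %/% blockSize
  blockMean <- blockStd <- numeric(nBlocks)
  for (b in seq_len(nBlocks)) {
    sel <- ((b - 1L) * blockSize + 1L):(b * blockSize)
    blockMean[b] <- mean(counts[sel])
    blockStd[b] <- stats::sd(counts[sel])
  }
  hw <- (window - 1L) %/% 2L
  smoothed <- vapply(seq_len(nBlocks), function(i)
    mean(blockMean[max(1L, i - hw):min(nBlocks, i + hw)]), 0)
  list(counts = counts, blockMean = blockMean, blockStd = blockStd,
       smoothed = smoothed)
}
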