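#' Split a volume into four checkerboard sub-volumes
#'
#' 2x2 decimation along the lateral (x) and elevation (y) axes: the four
#' sub-volumes take the (even, even), (odd, odd), (even, odd) and
#' (odd, even) samples, so reassembling them reproduces the original
#' exactly and the sub-voxel spacing doubles along the split axes. The
#' complementary pairs used for single-image FSC are (ee, oo) and
#' (eo, oe). Odd dimensions along the split axes are trimmed by one voxel
#' with a warning.
#'
#' @param volume 3-D array (z, x, y).
#' @param spacing voxel size of `volume` in mm (numeric(3) or scalar).
#' @return list with `sub` (list `ee`, `oo`, `eo`, `oe`), `pairs` (list of
#'   two character pairs), and `spacing` of the sub-volumes.
#' @export
splitFour <- function(volume, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(volume)
  if (d[2] %% 2L || d[3] %% 2L) {
    warning("odd dimension along a split axis; trimming by one voxel")
    volume <- volume[, seq_len(d[2] - d[2] %% 2L),
                     seq_len(d[3] - d[3] %% 2L), drop = FALSE]
    d <- dim(volume)
  }
  ix <- list(e = seq(1L, d[2], by = 2L), o = seq(2L, d[2], by = 2L))
  iy <- list(e = seq(1L, d[3], by = 2L), o = seq(2L, d[3], by = 2L))
  sub <- list(ee = volume[, ix$e, iy$e, drop = FALSE],
              oo = volume[, ix$o, iy$o, drop = FALSE],
              eo = volume[, ix$e, iy$o, drop = FALSE],
              oe = volume[, ix$o, iy$e, drop = FALSE])
  list(sub = sub,
       pairs = list(c("ee", "oo"), c("eo", "oe")),
       spacing = spacing * c(1, 2, 2))
}

#' Fourier shell correlation of two volumes
#'
#' `FSC(r) = Re[sum_shell F1 conj(F2)] / sqrt(sum_shell |F1|^2 *
#' sum_shell |F2|^2)` over spherical shells of one frequency bin around
#' the DC-centered radius, with per-axis frequencies in physical units
#' (1/um) so anisotropic voxels are handled. Invariant to global intensity
#' scaling of either input.
#'
#' @param v1,v2 3-D arrays of identical shape.
#' @param spacing voxel size in mm (numeric(3) or scalar).
#' @return data.frame with `freq` (shell center, 1/um), `fsc`, `n`
#'   (voxels per shell); empty shells are dropped.
#' @export
fscCurve <- function(v1, v2, spacing) {
  if (!identical(dim(v1), dim(v2))) stop("volumes must share a shape")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(v1)
  F1 <- stats::fft(v1)
  F2 <- stats::fft(v2)
  spUm <- spacing * 1e3
  fr <- lapply(1:3, function(ax) {
    k <- seq_len(d[ax]) - 1L
    k[k > d[ax] / 2] <- k[k > d[ax] / 2] - d[ax]
    k / (d[ax] * spUm[ax])
  })
  rad <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+"))
  df <- max(1 / (d * spUm))
  shell <- as.integer(round(rad / df))
  nyq <- min(1 / (2 * spUm))
  keep <- rad <= nyq
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  sNum <- tapply(num[keep], shell[keep], sum)
  sP1 <- tapply(p1[keep], shell[keep], sum)
  sP2 <- tapply(p2[keep], shell[keep], sum)
  n <- tapply(rep(1L, sum(keep)), shell[keep], sum)
  den <- sqrt(sP1 * sP2)
  ok <- den > 0
  out <- data.frame(freq = as.integer(names(sNum))[ok] * df,
                    fsc = as.numeric(sNum[ok] / den[ok]),
                    n = as.integer(n[ok]))
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  out
}

#' Half-bit information threshold curve
#'
#' Shell-size-dependent significance threshold corresponding to half a bit
#' of information per voxel:
#' `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))`.
#' Decreases monotonically with `n` towards the asymptote
#' `0.2071 / 1.2071 ~= 0.1716`.
#'
#' @param n voxels per shell (vector).
#' @return threshold per shell.
#' @export
halfBitThreshold <- function(n) {
  if (any(n < 1)) stop("n must be >= 1")
  (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))
}

#' Single-image FSC resolution estimate
#'
#' Splits the rendered volume into four checkerboard sub-volumes
#' ([splitFour()]), computes the FSC of the two complementary pairs on the
#' doubled sub-voxel spacing, averages the two curves (shells are
#' identical by construction), and intersects with the half-bit threshold.
#' The resolution is `1 / f_cross` at the first frequency where the
#' averaged FSC drops below the threshold after having been above it;
#' single-shell dips followed by at least `spikeTolerance + 1` shells back
#' above the threshold are ignored.
#'
#' @param volume 3-D array on the rendering grid, or a
#'   [SuperResVolume-class] (its intensity volume is used).
#' @param spacing voxel size in mm (ignored for a `SuperResVolume`).
#' @param spikeTolerance number of consecutive sub-threshold shells
#'   tolerated as a spike (default 1; 0 disables).
#' @return list of class `FSCResult`: `curve` (data.frame `freq`, `fsc`,
#'   `n`, `threshold`), `resolutionUm` (`Inf` when the curve never
#'   crosses, i.e. resolution beyond Nyquist), `nyquistUm`.
#' @export
singleImageFsc <- function(volume, spacing = NULL, spikeTolerance = 1L) {
  if (is(volume, "SuperResVolume")) {
    spacing <- gridSpacing(volume)
    volume <- intensityVolume(volume)
  }
  if (is.null(spacing)) stop("spacing is required for a plain array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sp <- splitFour(volume, spacing)
  c1 <- fscCurve(sp$sub[[sp$pairs[[1]][1]]], sp$sub[[sp$pairs[[1]][2]]],
                 sp$spacing)
  c2 <- fscCurve(sp$sub[[sp$pairs[[2]][1]]], sp$sub[[sp$pairs[[2]][2]]],
                 sp$spacing)
  if (!isTRUE(all.equal(c1$freq, c2$freq)))
    stop("shells differ between the two sub-image pairs")
  curve <- data.frame(freq = c1$freq, fsc = (c1$fsc + c2$fsc) / 2,
                      n = c1$n + c2$n)
  curve$threshold <- halfBitThreshold(curve$n)
  res <- firstCrossing(curve$freq, curve$fsc, curve$threshold, spikeTolerance)
  structure(list(curve = curve,
                 resolutionUm = if (is.na(res)) Inf else 1 / res,
                 nyquistUm = 2 * max(sp$spacing) * 1e3),
            class = "FSCResult")
}

firstCrossing <- function(freq, fsc, thr, spikeTolerance) {
  above <- fsc >= thr
  n <- length(fsc)
  started <- FALSE
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      started <- TRUE
    } else if (started) {
      run <- 0L
      j <- i
      while (j <= n && !above[j]) { run <- run + 1L; j <- j + 1L }
      if (run <= spikeTolerance && j <= n) {
        i <- j
        next
      }
      return(freq[i])
    }
    i <- i + 1L
  }
  NA_real_
}
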