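#' Plane-wave transmission and reception scheme
#'
#' @param angles m x 2 matrix of (lateral, elevation) tilts in degrees;
#'   default the 5-angle set (0,0), (+-3,0), (0,+-3).
#' @param soundSpeed m/s.
#' @param sampleRate Hz; taken from the RF dataset when `NULL`.
#' @param apodization `"none"` (default) or `"fnumber"` to restrict each
#'   voxel's receive aperture to elements within `z / (2 F)` laterally.
#' @param fnumber receive F-number used when `apodization = "fnumber"`.
#' @return list of class `PlaneWaveScheme`.
#' @export
planeWaveScheme <- function(angles = defaultAngles(), soundSpeed = 1540,
                            sampleRate = NULL,
                            apodization = c("none", "fnumber"),
                            fnumber = 1) {
  angles <- rbindable(angles)
  if (nrow(angles) < 1L) stop("at least one angle is required")
  structure(list(angles = angles, soundSpeed = soundSpeed,
                 sampleRate = sampleRate,
                 apodization = match.arg(apodization), fnumber = fnumber),
            class = "PlaneWaveScheme")
}

#' Plane-wave transmit delay
#'
#' Time for a tilted plane wave leaving the array plane at t = 0 to reach a
#' voxel. The composite dual-tilt wavefront travels along the unit vector
#' with direction cosines `(sqrt(1 - sin^2 a_lat - sin^2 a_elev),
#' sin a_lat, sin a_elev)` in (z, x, y); for a single tilt this reduces to
#' the familiar `(z cos a + x sin a) / c`.
#'
#' @param voxel position(s) (z, x, y) in mm; vector or n x 3 matrix.
#' @param angle (lateral, elevation) tilt in degrees, each `< 90` in
#'   magnitude.
#' @param soundSpeed m/s.
#' @return delay(s) in seconds.
#' @examples
#' transmitDelay(c(10, 0, 0), c(0, 0), 1540)  # 10 mm / c
#' @export
transmitDelay <- function(voxel, angle, soundSpeed = 1540) {
  if (any(abs(angle) >= 90)) stop("angle magnitudes must be < 90 degrees")
  v <- rbindable(voxel)
  sx <- sin(angle[1] * pi / 180)
  sy <- sin(angle[2] * pi / 180)
  sz <- sqrt(max(0, 1 - sx^2 - sy^2))
  drop((v[, 1] * sz + v[, 2] * sx + v[, 3] * sy) * 1e-3 / soundSpeed)
}

#' Delay-and-sum beamforming of plane-wave RF data
#'
#' For every voxel of the imaging grid and every plane-wave angle, channel
#' traces are sampled (linear inter-sample interpolation, out-of-range
#' samples contribute zero) at the transmit-plus-receive delay and summed
#' over elements. Returns one single-frame [VolumeSequence-class] per
#' angle; compound them with [compoundAngles()].
#'
#' @param rf an `RFData` dataset from [simulateRf()] (or with the same
#'   structure).
#' @param grid the beamforming [ImagingGrid-class] (typically lambda/2
#'   isotropic).
#' @param scheme a [planeWaveScheme()]; defaults to the angles/speed stored
#'   in `rf`.
#' @param frameRate nominal frame rate attached to the output volumes.
#' @param analytic beamform the analytic (Hilbert-transformed) traces,
#'   producing complex volumes whose modulus is the envelope (default);
#'   `FALSE` sums the raw RF samples.
#' @return list of [VolumeSequence-class], one per angle.
#' @export
dasBeamform <- function(rf, grid, scheme = NULL, frameRate = 1,
                        analytic = TRUE) {
  if (is.null(scheme))
    scheme <- planeWaveScheme(rf$angles, rf$soundSpeed, rf$sampleRate)
  fs <- scheme$sampleRate %||% rf$sampleRate
  c0 <- scheme$soundSpeed
  d <- gridDim(grid)
  vox <- voxelCoords(grid)          # nVox x 3 (z, x, y) mm
  elem <- elementPositions(rf$probe)
  nS <- dim(rf$rf)[1]
  out <- vector("list", nrow(scheme$angles))
  for (ai in seq_len(nrow(scheme$angles))) {
    tauTx <- transmitDelay(vox, scheme$angles[ai, ], c0)
    trace <- rf$rf[, , ai]
    if (analytic && !is.complex(trace)) trace <- hilbertMatrix(trace)
    acc <- if (is.complex(trace)) complex(nrow(vox)) else numeric(nrow(vox))
    for (e in seq_len(nrow(elem))) {
      dz <- vox[, 1] - elem[e, 1]
      dx <- vox[, 2] - elem[e, 2]
      dy <- vox[, 3] - elem[e, 3]
      tau <- tauTx + sqrt(dz^2 + dx^2 + dy^2) * 1e-3 / c0
      s <- (tau - rf$t0) * fs + 1
      i0 <- floor(s)
      w <- s - i0
      ok <- i0 >= 1L & i0 < nS
      if (scheme$apodization == "fnumber")
        ok <- ok & sqrt(dx^2 + dy^2) <= dz / (2 * scheme$fnumber)
      if (!any(ok)) next
      tr <- trace[, e]
      acc[ok] <- acc[ok] + tr[i0[ok]] * (1 - w[ok]) + tr[i0[ok] + 1L] * w[ok]
    }
    if (all(acc == 0))
      warning("beamforming grid appears to lie outside the insonified region")
    out[[ai]] <- volumeSequence(array(acc, c(d, 1L)), grid, frameRate)
  }
  out
}

# analytic signal of each column (FFT Hilbert transform along rows)
hilbertMatrix <- function(m) {
  n <- nrow(m)
  fm <- stats::mvfft(m)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(fm * h, inverse = TRUE) / n
}

voxelCoords <- function(grid) {
  d <- gridDim(grid)
  o <- gridOrigin(grid)
  s <- gridSpacing(grid)
  z <- o[1] + (seq_len(d[1]) - 1) * s[1]
  x <- o[2] + (seq_len(d[2]) - 1) * s[2]
  y <- o[3] + (seq_len(d[3]) - 1) * s[3]
  cbind(rep(z, times = d[2] * d[3]),
        rep(rep(x, each = d[1]), times = d[3]),
        rep(y, each = d[1] * d[2]))
}

#' Coherent compounding across plane-wave angles
#'
#' Voxelwise mean of the per-angle beamformed volumes (coherent: performed
#' on the pre-envelope samples).
#'
#' @param volumes list of [VolumeSequence-class] sharing one grid and
#'   frame count.
#' @return a single [VolumeSequence-class].
#' @export
compoundAngles <- function(volumes) {
  g <- imagingGridOf(volumes[[1]])
  for (v in volumes[-1]) {
    gv <- imagingGridOf(v)
    if (!isTRUE(all.equal(gridDim(gv), gridDim(g))) ||
        !isTRUE(all.equal(gridSpacing(gv), gridSpacing(g))) ||
        !isTRUE(all.equal(gridOrigin(gv), gridOrigin(g))) ||
        nFrames(v) != nFrames(volumes[[1]]))
      stop("volumes must share one grid and frame count")
  }
  acc <- frameArray(volumes[[1]])
  for (v in volumes[-1]) acc <- acc + frameArray(v)
  volumeSequence(acc / length(volumes), g, frameRate(volumes[[1]]))
}

#' Envelope detection
#'
#' Magnitude of the analytic signal along the axial axis (per lateral/
#' elevation line and frame). Complex input is already analytic, so its
#' modulus is returned; non-negative real input (the synthetic B-mode path)
#' is already an envelope and passes through unchanged.
#'
#' @param seq a [VolumeSequence-class].
#' @return a real, non-negative [VolumeSequence-class].
#' @export
envelopeDetect <- function(seq) {
  a <- frameArray(seq)
  if (is.complex(a))
    return(volumeSequence(Mod(a), imagingGridOf(seq), frameRate(seq)))
  if (all(a >= 0)) return(seq)
  d <- dim(a)
  analytic <- hilbertMatrix(matrix(a, nrow = d[1]))
  volumeSequence(array(Mod(analytic), d), imagingGridOf(seq), frameRate(seq))
}
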