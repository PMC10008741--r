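#' Localization parameters
#'
#' @param noiseThresholdFrac noise floor as a fraction of the per-frame
#'   maximum intensity (typical range 0.01-0.07, default 0.03).
#' @param segmentKStd segmentation threshold in standard deviations above
#'   the mean intensity of the (noise-thresholded, PSF-convolved) frame;
#'   typical range 1-4. Defaults 1.5 for the low pass, 3.5 for the high
#'   pass of [dualPassLocalize()].
#' @param psf a [psfModel()] for the matched filter.
#' @param connectivity blob connectivity, 6, 18 or 26 (default 26).
#' @param minBlobVoxels blobs smaller than this are dropped (default 2).
#' @param weightsFrom `"convolved"` (default; centroid weights taken from
#'   the matched-filtered frame, the volume the segmentation operates on)
#'   or `"raw"` (weights from the noise-thresholded envelope).
#' @return list of class `LocalizeConfig`.
#' @export
localizeConfig <- function(noiseThresholdFrac = 0.03, segmentKStd = 1.5,
                           psf = psfModel(), connectivity = 26L,
                           minBlobVoxels = 2L,
                           weightsFrom = c("convolved", "raw")) {
  if (noiseThresholdFrac <= 0 || noiseThresholdFrac >= 1)
    stop("noiseThresholdFrac must be in (0, 1)")
  if (segmentKStd <= 0) stop("segmentKStd must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(noiseThresholdFrac = noiseThresholdFrac,
                 segmentKStd = segmentKStd, psf = psf,
                 connectivity = as.integer(connectivity),
                 minBlobVoxels = as.integer(minBlobVoxels),
                 weightsFrom = match.arg(weightsFrom)),
            class = "LocalizeConfig")
}

#' Normalize a volume and zero low-intensity noise
#'
#' The volume is scaled to a maximum of 1 and values below `frac` are set
#' to zero. An all-zero volume is returned unchanged with a warning.
#'
#' @param volume non-negative 3-D array (envelope intensities).
#' @param frac noise floor as a fraction of the maximum (`frac = 0` only
#'   normalizes).
#' @return thresholded array with max 1.
#' @export
noiseThreshold <- function(volume, frac) {
  mx <- max(volume)
  if (mx <= 0) {
    warning("all-zero volume; returning unchanged")
    return(volume)
  }
  v <- volume / mx
  v[v < frac] <- 0
  v
}

#' PSF-matched Gaussian filtering
#'
#' Convolution with a unit-sum anisotropic 3-D Gaussian calibrated to the
#' point spread function: `sigma_axis = FWHM_axis / (2 sqrt(2 log 2))`,
#' kernel half-width `ceiling(3 sigma)`, reflective boundaries. Away from
#' the boundary the unit-sum kernel conserves total intensity.
#'
#' @param volume 3-D array.
#' @param psf a [psfModel()] (FWHMs in mm).
#' @param spacing voxel size in mm, numeric(3) (z, x, y) or scalar.
#' @return filtered array.
#' @export
matchFilter <- function(volume, psf, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sigVox <- psfSigmaMm(psf) / spacing
  gaussSmooth3(volume, sigVox)
}

#' Segment supra-threshold blobs
#'
#' Binary mask `volume > mean(volume) + kStd * sd(volume)` (statistics over
#' the whole frame), connected components under the stated connectivity,
#' components smaller than `minBlobVoxels` dropped. An empty mask yields
#' zero blobs.
#'
#' @param volume 3-D array.
#' @param kStd threshold in standard deviations above the mean.
#' @param connectivity 6, 18 or 26.
#' @param minBlobVoxels minimum voxels per retained blob.
#' @return list with `labels` (integer array, 0 = background, blobs
#'   numbered 1..n) and `nBlobs`.
#' @export
segmentBlobs <- function(volume, kStd, connectivity = 26L,
                         minBlobVoxels = 2L) {
  if (kStd <= 0) stop("kStd must be > 0")
  thr <- mean(volume) + kStd * stats::sd(volume)
  mask <- volume > thr
  labels <- array(0L, dim(volume))
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, nBlobs = 0L))
  d <- dim(volume)
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- connectivityOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    zz <- coords[, 1] + offs[j, 1]
    xx <- coords[, 2] + offs[j, 2]
    yy <- coords[, 3] + offs[j, 3]
    ok <- zz >= 1L & zz <= d[1] & xx >= 1L & xx <= d[2] & yy >= 1L & yy <= d[3]
    if (!any(ok)) next
    nb <- rank[cbind(zz[ok], xx[ok], yy[ok])]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  keep <- which(sizes >= minBlobVoxels)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[idx] <- relabel[memb]
  list(labels = labels, nBlobs = length(keep))
}

# half-space neighbor offsets (each undirected pair counted once)
connectivityOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  nnz <- rowSums(g != 0)
  g <- switch(as.character(connectivity),
              "6" = g[nnz == 1, , drop = FALSE],
              "18" = g[nnz >= 1 & nnz <= 2, , drop = FALSE],
              "26" = g[nnz >= 1, , drop = FALSE])
  pos <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[pos, , drop = FALSE]
}

#' Intensity-weighted centroid of a blob
#'
#' `position = sum(w_i * coord_i) / sum(w_i)` in physical mm under the
#' voxel-center convention — the sub-voxel localization estimate.
#'
#' @param voxels n x 3 matrix of voxel indices (z, x, y).
#' @param weights non-negative intensities, one per voxel.
#' @param grid the [ImagingGrid-class] the indices refer to.
#' @return numeric(3) position in mm, or `NULL` when the total weight is
#'   zero (blob discarded).
#' @export
weightedCentroid <- function(voxels, weights, grid) {
  voxels <- rbindable(voxels)
  if (any(weights < 0)) stop("weights must be >= 0")
  W <- sum(weights)
  if (W <= 0) return(NULL)
  idx <- colSums(voxels * weights) / W
  drop(voxelToPhys(grid, idx))
}

#' Single localization pass over a volume sequence
#'
#' Per frame: [noiseThreshold()] then [matchFilter()] then [segmentBlobs()]
#' then [weightedCentroid()] per blob, with centroid weights taken from the
#' convolved volume (configurable). Frames are processed independently.
#'
#' @param seq envelope-detected [VolumeSequence-class].
#' @param config a [localizeConfig()].
#' @param passLabel label stored with each localization (e.g. `"low"`).
#' @return data.frame with columns `pass`, `frame`, `z_mm`, `x_mm`,
#'   `y_mm`, `intensity` (blob-summed weight), `on_border`.
#' @export
localizePass <- function(seq, config, passLabel = "low") {
  stopifnot(inherits(config, "LocalizeConfig"))
  a <- frameArray(seq)
  if (is.complex(a)) stop("sequence must be envelope-detected (real)")
  g <- imagingGridOf(seq)
  d <- gridDim(g)
  out <- vector("list", nFrames(seq))
  for (t in seq_len(nFrames(seq))) {
    vol <- a[, , , t]
    if (max(vol) <= 0) next
    v <- noiseThreshold(vol, config$noiseThresholdFrac)
    cv <- matchFilter(v, config$psf, gridSpacing(g))
    seg <- segmentBlobs(cv, config$segmentKStd, config$connectivity,
                        config$minBlobVoxels)
    if (seg$nBlobs == 0L) next
    wsrc <- if (config$weightsFrom == "convolved") cv else v
    idx <- which(seg$labels > 0L)
    lab <- seg$labels[idx]
    coords <- arrayInd(idx, d)
    rows <- vector("list", seg$nBlobs)
    for (b in seq_len(seg$nBlobs)) {
      sel <- lab == b
      vx <- coords[sel, , drop = FALSE]
      w <- wsrc[idx[sel]]
      p <- weightedCentroid(vx, w, g)
      if (is.null(p)) next
      border <- any(vx == 1L) || any(sweep(vx, 2, d, "-") == 0L)
      rows[[b]] <- data.frame(pass = passLabel, frame = t, z_mm = p[1],
                              x_mm = p[2], y_mm = p[3], intensity = sum(w),
                              on_border = border)
    }
    out[[t]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(pass = character(0), frame = integer(0),
                      z_mm = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), intensity = numeric(0),
                      on_border = logical(0))
  rownames(res) <- NULL
  res
}

#' Dual-threshold localization
#'
#' Runs the same localization algorithm twice with a low and a high
#' segmentation threshold. The low pass keeps dim bubbles that a high
#' threshold would discard; the high pass separates closely spaced bright
#' bubbles that merge into one blob under the low threshold. The two
#' labeled sets are returned together; fusion happens at the rendering
#' stage ([fusePasses()]).
#'
#' @param seq envelope-detected [VolumeSequence-class].
#' @param lowConfig,highConfig [localizeConfig()]s with
#'   `lowConfig$segmentKStd <= highConfig$segmentKStd`.
#' @return data.frame as in [localizePass()], `pass` column `"low"` /
#'   `"high"`.
#' @export
dualPassLocalize <- function(seq, lowConfig = localizeConfig(segmentKStd = 1.5),
                             highConfig = localizeConfig(segmentKStd = 3.5)) {
  if (lowConfig$segmentKStd > highConfig$segmentKStd)
    stop("lowConfig must use the smaller segmentKStd")
  rbind(localizePass(seq, lowConfig, "low"),
        localizePass(seq, highConfig, "high"))
}
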