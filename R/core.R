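#' Construct an imaging grid
#'
#' @param origin numeric(3) physical position (mm) of the center of voxel
#'   (1,1,1), order (z, x, y).
#' @param spacing numeric(3) or scalar voxel size in mm.
#' @param dim integer(3) voxel counts (z, x, y).
#' @return an [ImagingGrid-class].
#' @examples
#' g <- imagingGrid(c(5, -2, -2), 0.0986, c(32, 48, 48))
#' voxelToPhys(g, c(1, 1, 1))
#' @export
imagingGrid <- function(origin, spacing, dim) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(origin) == 1L) origin <- rep(origin, 3L)
  new("ImagingGrid", origin = as.numeric(origin),
      spacing = as.numeric(spacing), dim = as.integer(dim))
}

#' Construct a volume sequence
#'
#' @param data 4-D array (z, x, y, t), real or complex.
#' @param grid an [ImagingGrid-class] matching the spatial dims.
#' @param frameRate volumes per second.
#' @return a [VolumeSequence-class].
#' @export
volumeSequence <- function(data, grid, frameRate) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  new("VolumeSequence", data = data, grid = grid,
      frameRate = as.numeric(frameRate))
}

#' Construct a matrix-array probe geometry
#'
#' Elements form a planar regular lattice centered on the origin of the
#' transducer plane (z = 0). Defaults are a 1024-element 32x32 array with
#' 0.3 mm pitch at 7.81 MHz, 60% fractional bandwidth.
#'
#' @param nx,ny element counts (lateral, elevation).
#' @param pitch element pitch in mm.
#' @param centerFrequency Hz.
#' @param fractionalBandwidth dimensionless.
#' @return a [ProbeGeometry-class].
#' @export
probeGeometry <- function(nx = 32L, ny = 32L, pitch = 0.3,
                          centerFrequency = 7.81e6,
                          fractionalBandwidth = 0.6) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pitch
  ys <- (seq_len(ny) - (ny + 1) / 2) * pitch
  pos <- cbind(z = 0, x = rep(xs, times = ny), y = rep(ys, each = nx))
  new("ProbeGeometry", nx = nx, ny = ny, pitch = pitch,
      centerFrequency = centerFrequency,
      fractionalBandwidth = fractionalBandwidth, positions = pos)
}

#' Acoustic wavelength in micrometres
#'
#' `lambda = c / f0`. At the 7.81 MHz center frequency of the matrix array
#' and 1540 m/s soft-tissue sound speed this gives 197.2 um, so the lambda/2
#' beamforming voxel is 98.6 um and the lambda/20 rendering voxel 9.86 um.
#'
#' @param centerFrequency Hz, > 0.
#' @param soundSpeed m/s, > 0 (default 1540, soft tissue).
#' @return wavelength in micrometres.
#' @examples
#' wavelength(7.81e6) / 2   # lambda/2 beamforming voxel, um
#' wavelength(7.81e6) / 20  # lambda/20 rendering voxel, um
#' @export
wavelength <- function(centerFrequency, soundSpeed = 1540) {
  if (!is.finite(centerFrequency) || centerFrequency <= 0)
    stop("centerFrequency must be > 0")
  if (!is.finite(soundSpeed) || soundSpeed <= 0)
    stop("soundSpeed must be > 0")
  soundSpeed / centerFrequency * 1e6
}

#' Voxel index to physical coordinate and back
#'
#' Voxel-center convention with 1-based indices: voxel (1,1,1) sits at the
#' grid origin. `physToVoxel` returns fractional (real-valued) indices;
#' round them to get the containing voxel. The mapping is a bijection on
#' the voxel lattice.
#'
#' @param grid an [ImagingGrid-class].
#' @param idx numeric vector of length 3 or n x 3 matrix of (possibly
#'   fractional) voxel indices (z, x, y).
#' @param pos numeric vector of length 3 or n x 3 matrix of physical
#'   positions in mm (z, x, y).
#' @return matrix (or vector) of positions in mm / fractional indices.
#' @export
voxelToPhys <- function(grid, idx) {
  idx <- rbindable(idx)
  sweep(sweep(idx - 1, 2, gridSpacing(grid), "*"), 2, gridOrigin(grid), "+") |>
    dropIfVector(idx)
}

#' @rdname voxelToPhys
#' @export
physToVoxel <- function(grid, pos) {
  pos <- rbindable(pos)
  p <- sweep(sweep(pos, 2, gridOrigin(grid), "-"), 2, gridSpacing(grid), "/") + 1
  dropIfVector(p, pos)
}

rbindable <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  else as.matrix(x)
}

dropIfVector <- function(res, orig) {
  if (nrow(res) == 1L && nrow(orig) == 1L) drop(res) else res
}

#' Describe an acquisition plan
#'
#' Bundles the counts the streaming acquisition is parameterized by: number
#' of plane-wave transmits per compounded volume, RF samples per channel per
#' transmit, volumes per acquisition block, number of synchronized systems
#' and channels per system, bytes per RF sample, the volume rate, and the
#' total number of volumes. `blockBytesPerSystem` normally derives from the
#' counts (`samplesPerChannel * nAngles * volumesPerBlock *
#' channelsPerSystem * bytesPerSample`) but can be overridden with a
#' measured value, in which case the storage totals are scaled from it.
#'
#' @param nAngles plane-wave transmits per volume.
#' @param samplesPerChannel RF samples per channel per transmit.
#' @param volumesPerBlock volumes per acquisition block.
#' @param nSystems synchronized scanner systems.
#' @param channelsPerSystem receive channels per system.
#' @param bytesPerSample bytes per stored RF sample (default 2, 16-bit).
#' @param volumeRate volumes per second.
#' @param totalVolumes total volumes in the acquisition; must be a multiple
#'   of `volumesPerBlock`.
#' @param blockBytesPerSystem optional measured per-system block size in
#'   bytes, overriding the derived value.
#' @return a list of class `AcquisitionPlan`.
#' @examples
#' # 4-system 1024-channel scheme: 5 angles, 100-volume blocks, 500 vps
#' p <- acquisitionPlan(nAngles = 5, samplesPerChannel = 1024,
#'                      volumesPerBlock = 100, nSystems = 4,
#'                      channelsPerSystem = 256, volumeRate = 500,
#'                      totalVolumes = 1e5, blockBytesPerSystem = 245e6)
#' planAcquisition(p)$totalDurationS  # 200 s
#' @export
acquisitionPlan <- function(nAngles, samplesPerChannel, volumesPerBlock,
                            nSystems, channelsPerSystem, bytesPerSample = 2,
                            volumeRate, totalVolumes,
                            blockBytesPerSystem = NULL) {
  counts <- c(nAngles, samplesPerChannel, volumesPerBlock, nSystems,
              channelsPerSystem, bytesPerSample, totalVolumes)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (volumeRate <= 0) stop("volumeRate must be > 0")
  if (totalVolumes %% volumesPerBlock != 0)
    stop("totalVolumes must be divisible by volumesPerBlock")
  structure(list(nAngles = nAngles, samplesPerChannel = samplesPerChannel,
                 volumesPerBlock = volumesPerBlock, nSystems = nSystems,
                 channelsPerSystem = channelsPerSystem,
                 bytesPerSample = bytesPerSample, volumeRate = volumeRate,
                 totalVolumes = totalVolumes,
                 blockBytesPerSystem = blockBytesPerSystem),
            class = "AcquisitionPlan")
}

#' Acquisition timing and storage arithmetic
#'
#' Exact rational arithmetic over an [acquisitionPlan()]: block and total
#' durations from the volume rate, and per-block / whole-dataset storage
#' from the per-system block size times the system and block counts.
#'
#' @param plan an `AcquisitionPlan`.
#' @return list with `blockBytesPerSystem`, `blockBytesTotal`,
#'   `datasetBytesTotal`, `blockDurationS`, `totalDurationS`, `nBlocks`.
#' @export
planAcquisition <- function(plan) {
  stopifnot(inherits(plan, "AcquisitionPlan"))
  perSys <- plan$blockBytesPerSystem
  if (is.null(perSys))
    perSys <- plan$samplesPerChannel * plan$nAngles * plan$volumesPerBlock *
      plan$channelsPerSystem * plan$bytesPerSample
  nBlocks <- plan$totalVolumes / plan$volumesPerBlock
  blockTotal <- plan$nSystems * perSys
  list(blockBytesPerSystem = perSys,
       blockBytesTotal = blockTotal,
       datasetBytesTotal = blockTotal * nBlocks,
       blockDurationS = plan$volumesPerBlock / plan$volumeRate,
       totalDurationS = plan$totalVolumes / plan$volumeRate,
       nBlocks = nBlocks)
}
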