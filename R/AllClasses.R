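#' @import methods
NULL

#' Regular 3-D imaging grid
#'
#' Axis order throughout the package is (axial z, lateral x, elevation y).
#' Voxel centers are at `origin + (index - 1) * spacing` (1-based indices,
#' voxel-center convention); all physical lengths are millimetres.
#'
#' @slot origin numeric(3), physical coordinate (mm) of the center of voxel
#'   (1,1,1), in (z, x, y) order.
#' @slot spacing numeric(3), strictly positive voxel size in mm.
#' @slot dim integer(3), number of voxels per axis.
#'
#' @seealso [imagingGrid()], [voxelToPhys()], [physToVoxel()]
#' @exportClass ImagingGrid
setClass("ImagingGrid",
  representation(origin = "numeric", spacing = "numeric", dim = "integer"))

setValidity("ImagingGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (length(object@dim) != 3L) return("dim must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be strictly positive")
  if (any(object@dim < 1L)) return("dim must be >= 1")
  TRUE
})

#' Time-ordered sequence of 3-D volumes
#'
#' A 4-D array in (z, x, y, time) layout on a shared [ImagingGrid-class],
#' sampled at a fixed volumetric frame rate. Samples may be real
#' (envelope/B-mode intensities) or complex (pre-envelope beamformed data).
#'
#' @slot data 4-D numeric or complex array, dims (nz, nx, ny, nt).
#' @slot grid the common [ImagingGrid-class].
#' @slot frameRate volumes per second, > 0.
#'
#' @seealso [volumeSequence()]
#' @exportClass VolumeSequence
setClass("VolumeSequence",
  representation(data = "array", grid = "ImagingGrid", frameRate = "numeric"))

setValidity("VolumeSequence", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4-D array (z, x, y, t)")
  if (!identical(as.integer(d[1:3]), object@grid@dim))
    return("spatial dims of data do not match the grid")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a single positive number")
  TRUE
})

#' Matrix-array probe geometry
#'
#' Planar regular lattice of elements centered at the origin of the (x, y)
#' transducer plane at z = 0. Defaults describe a 32x32 matrix array with
#' 0.3 mm pitch and a 7.81 MHz center frequency with 60% bandwidth.
#'
#' @slot nx,ny element counts along lateral / elevation.
#' @slot pitch element pitch in mm.
#' @slot centerFrequency Hz.
#' @slot fractionalBandwidth dimensionless (0.6 = 60%).
#' @slot positions n x 3 matrix of element centers, columns (z, x, y) mm
#'   (z = 0 for a planar array).
#'
#' @seealso [probeGeometry()]
#' @exportClass ProbeGeometry
setClass("ProbeGeometry",
  representation(nx = "integer", ny = "integer", pitch = "numeric",
                 centerFrequency = "numeric", fractionalBandwidth = "numeric",
                 positions = "matrix"))

setValidity("ProbeGeometry", function(object) {
  if (object@pitch <= 0) return("pitch must be > 0")
  if (object@centerFrequency <= 0) return("centerFrequency must be > 0")
  if (nrow(object@positions) != object@nx * object@ny)
    return("element count must equal nx * ny")
  if (ncol(object@positions) != 3L) return("positions must be n x 3")
  ctr <- colMeans(object@positions)
  if (max(abs(ctr)) > 1e-9) return("element lattice must be centered at the origin")
  TRUE
})

#' Super-resolved accumulation volumes
#'
#' Track accumulations on the fine (lambda/20) rendering grid: per-voxel
#' visit counts (`intensity` and `density`, identical under the default
#' rasterizer but kept separate because intensity is what gets post-filtered
#' and fused while density is the divisor of the velocity map) and the
#' signed axial-velocity sum `vzSum` (mm/s accumulated over visiting track
#' segments).
#'
#' @slot grid rendering [ImagingGrid-class].
#' @slot intensity,density,vzSum 3-D arrays with dims equal to `grid` dims.
#' @slot clipped number of track points that fell outside the grid.
#'
#' @seealso [accumulateTracks()], [velocityMap()]
#' @exportClass SuperResVolume
setClass("SuperResVolume",
  representation(grid = "ImagingGrid", intensity = "array", density = "array",
                 vzSum = "array", clipped = "integer"))

setValidity("SuperResVolume", function(object) {
  d <- object@grid@dim
  for (s in c("intensity", "density", "vzSum"))
    if (!identical(as.integer(dim(slot(object, s))), d))
      return(sprintf("%s dims do not match the grid", s))
  if (any(object@density < 0)) return("density must be non-negative")
  TRUE
})

setMethod("show", "ImagingGrid", function(object) {
  cat("ImagingGrid:", paste(object@dim, collapse = " x "),
      "voxels (z, x, y)\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = ", "), "\n")
  cat("  origin  (mm):", paste(signif(object@origin, 4), collapse = ", "), "\n")
  cat("  extent  (mm):", paste(signif(object@dim * object@spacing, 4),
                               collapse = ", "), "\n")
})

setMethod("show", "VolumeSequence", function(object) {
  d <- dim(object@data)
  cat("VolumeSequence:", d[4], "frames of", paste(d[1:3], collapse = " x "),
      if (is.complex(object@data)) "complex" else "real", "voxels\n")
  cat("  frame rate:", object@frameRate, "volumes/s  (",
      signif(d[4] / object@frameRate, 4), "s )\n")
  cat("  voxel (mm):", paste(signif(object@grid@spacing, 4), collapse = ", "), "\n")
})

setMethod("show", "ProbeGeometry", function(object) {
  cat("ProbeGeometry:", object@nx, "x", object@ny, "matrix array, pitch",
      object@pitch, "mm\n")
  cat("  center frequency:", object@centerFrequency / 1e6, "MHz,",
      object@fractionalBandwidth * 100, "% bandwidth\n")
})

setMethod("show", "SuperResVolume", function(object) {
  cat("SuperResVolume:", paste(object@grid@dim, collapse = " x "),
      "voxels at", paste(signif(object@grid@spacing * 1e3, 3), collapse = "/"),
      "um\n")
  cat("  occupied voxels:", sum(object@density > 0), " clipped points:",
      object@clipped, "\n")
})
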