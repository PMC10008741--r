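#' Accessors for grid and sequence objects
#'
#' Slot access goes through these accessors; slots are internal.
#'
#' @param x an [ImagingGrid-class], [VolumeSequence-class],
#'   [ProbeGeometry-class] or [SuperResVolume-class].
#' @return `gridSpacing`, `gridOrigin`: numeric(3) in (z, x, y) mm.
#'   `gridDim`: integer(3). `frameArray`: the raw 4-D (z, x, y, t) array.
#'   `frameRate`: volumes/s. `nFrames`: frame count.
#'   `imagingGridOf`: the underlying [ImagingGrid-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("imagingGridOf", function(x) standardGeneric("imagingGridOf"))
#' @rdname accessors
#' @export
setGeneric("frameArray", function(x) standardGeneric("frameArray"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
setMethod("gridSpacing", "ImagingGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "ImagingGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridDim", "ImagingGrid", function(x) x@dim)
#' @rdname accessors
setMethod("imagingGridOf", "ImagingGrid", function(x) x)

#' @rdname accessors
setMethod("gridSpacing", "VolumeSequence", function(x) x@grid@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VolumeSequence", function(x) x@grid@origin)
#' @rdname accessors
setMethod("gridDim", "VolumeSequence", function(x) x@grid@dim)
#' @rdname accessors
setMethod("imagingGridOf", "VolumeSequence", function(x) x@grid)
#' @rdname accessors
setMethod("frameArray", "VolumeSequence", function(x) x@data)
#' @rdname accessors
setMethod("frameRate", "VolumeSequence", function(x) x@frameRate)
#' @rdname accessors
setMethod("nFrames", "VolumeSequence", function(x) dim(x@data)[4L])

#' @rdname accessors
setMethod("imagingGridOf", "SuperResVolume", function(x) x@grid)
#' @rdname accessors
setMethod("gridSpacing", "SuperResVolume", function(x) x@grid@spacing)
#' @rdname accessors
setMethod("gridDim", "SuperResVolume", function(x) x@grid@dim)
#' @rdname accessors
setMethod("gridOrigin", "SuperResVolume", function(x) x@grid@origin)

#' @rdname accessors
#' @export
setGeneric("intensityVolume", function(x) standardGeneric("intensityVolume"))
#' @rdname accessors
#' @export
setGeneric("densityVolume", function(x) standardGeneric("densityVolume"))
#' @rdname accessors
#' @export
setGeneric("vzSumVolume", function(x) standardGeneric("vzSumVolume"))
#' @rdname accessors
setMethod("intensityVolume", "SuperResVolume", function(x) x@intensity)
#' @rdname accessors
setMethod("densityVolume", "SuperResVolume", function(x) x@density)
#' @rdname accessors
setMethod("vzSumVolume", "SuperResVolume", function(x) x@vzSum)

#' @rdname accessors
#' @export
setGeneric("elementPositions", function(x) standardGeneric("elementPositions"))
#' @rdname accessors
setMethod("elementPositions", "ProbeGeometry", function(x) x@positions)
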