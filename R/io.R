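#' Read and write volume sequences
#'
#' Two on-disk representations are supported, chosen by file extension:
#'
#' * **NIfTI** (`.nii`): the 4-D (z, x, y, t) array is stored as float64,
#'   so a write/read round trip is bit-exact. Voxel spacing and the frame
#'   interval go into `pixdim`; grid origin and frame rate are duplicated
#'   in a JSON sidecar (`<file>.json`) next to the image.
#' * **TIFF** (`.tif`/`.tiff`): one 32-bit float page per (z, t) slice,
#'   page index `(t-1)*nz + z`. The TIFF writer stores values in \[0,1\],
#'   so data are min-max scaled and the slope/offset recorded in the JSON
#'   sidecar; round trips are exact to float32 precision of the scaled
#'   values.
#'
#' Only real-valued (envelope) sequences are serialized; complex
#' pre-envelope data live in memory only.
#'
#' @param seq a [VolumeSequence-class].
#' @param path output/input file path (`.nii`, `.tif` or `.tiff`).
#' @return `writeVolumeSequence` returns `path` invisibly;
#'   `readVolumeSequence` returns a [VolumeSequence-class].
#' @examples
#' g <- imagingGrid(c(0, 0, 0), 0.1, c(4, 4, 4))
#' vs <- volumeSequence(array(runif(4^3 * 2), c(4, 4, 4, 2)), g, 500)
#' f <- tempfile(fileext = ".nii")
#' writeVolumeSequence(vs, f)
#' identical(frameArray(readVolumeSequence(f)), frameArray(vs))
#' @export
writeVolumeSequence <- function(seq, path) {
  stopifnot(is(seq, "VolumeSequence"))
  if (is.complex(frameArray(seq)))
    stop("complex sequences are not serialized; take the envelope first")
  fmt <- ioFormat(path)
  meta <- list(axes = c("z", "x", "y", "t"),
               dim = as.integer(dim(frameArray(seq))),
               spacing_mm = gridSpacing(seq),
               origin_mm = gridOrigin(seq),
               frame_rate = frameRate(seq))
  if (fmt == "nifti") {
    img <- RNifti::asNifti(frameArray(seq))
    RNifti::pixdim(img) <- c(gridSpacing(seq), 1 / frameRate(seq))
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    a <- frameArray(seq)
    rng <- range(a)
    slope <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    meta$tiff_scale <- list(slope = slope, offset = rng[1])
    d <- dim(a)
    pages <- vector("list", d[1] * d[4])
    k <- 0L
    for (t in seq_len(d[4])) for (z in seq_len(d[1])) {
      k <- k + 1L
      pages[[k]] <- (a[z, , , t] - rng[1]) / slope
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVolumeSequence
#' @export
readVolumeSequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- ioFormat(path)
  meta <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else list()
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    a <- array(as.vector(img), dim(img))
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    pd <- RNifti::pixdim(img)
    spacing <- meta$spacing_mm %||% pd[1:3]
    fr <- meta$frame_rate %||%
      (if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) 1 / pd[4] else NULL)
  } else {
    if (is.null(meta$dim))
      stop("malformed TIFF sequence: sidecar ", sidecarPath(path),
           " with field 'dim' is required")
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- as.integer(meta$dim)
    if (length(pages) != d[1] * d[4])
      stop("malformed TIFF sequence: expected ", d[1] * d[4],
           " pages, found ", length(pages), " (field 'dim')")
    a <- array(0, d)
    k <- 0L
    for (t in seq_len(d[4])) for (z in seq_len(d[1])) {
      k <- k + 1L
      a[z, , , t] <- pages[[k]]
    }
    if (!is.null(meta$tiff_scale))
      a <- a * meta$tiff_scale$slope + meta$tiff_scale$offset
    spacing <- meta$spacing_mm
    fr <- meta$frame_rate
    if (is.null(spacing))
      stop("malformed TIFF sequence: missing field 'spacing_mm'")
  }
  if (is.null(fr))
    stop("malformed volume sequence ", path, ": missing field 'frame_rate'")
  origin <- meta$origin_mm %||% c(0, 0, 0)
  volumeSequence(a, imagingGrid(origin, spacing, dim(a)[1:3]), fr)
}

ioFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nii = "nifti",
         tif = ,
         tiff = "tiff",
         stop("unsupported volume format '.", ext, "' (use .nii or .tif)"))
}

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

`%||%` <- function(a, b) if (is.null(a)) b else a
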