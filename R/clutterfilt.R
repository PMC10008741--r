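#' Casorati (space x time) matrix of a volume sequence
#'
#' Column t is frame t flattened in fixed (z, x, y) raster order (z fastest,
#' the native column-major layout), so `uncasorati(casorati(x), dim)` is an
#' exact inverse and column norms equal frame norms.
#'
#' @param x a [VolumeSequence-class] or 4-D (z, x, y, t) array.
#' @return matrix with `prod(spatial dims)` rows and one column per frame.
#' @export
casorati <- function(x) {
  a <- if (is(x, "VolumeSequence")) frameArray(x) else x
  d <- dim(a)
  if (length(d) != 4L) stop("expected a 4-D (z, x, y, t) array")
  matrix(a, nrow = prod(d[1:3]), ncol = d[4],
         dimnames = NULL)
}

#' @rdname casorati
#' @param m a Casorati matrix.
#' @param spatialDim integer(3) spatial dims (z, x, y) to restore.
#' @export
uncasorati <- function(m, spatialDim) {
  array(m, c(as.integer(spatialDim), ncol(m)))
}

#' SVD clutter filtering
#'
#' Block-wise singular-value-decomposition filter that isolates microbubble
#' signal: within each temporal block of `blockSize` frames the Casorati
#' matrix `X = U S V*` has its `K = ceiling(removedFraction * n_t)` largest
#' singular values zeroed before reconstruction. Temporally coherent
#' clutter (tissue, skull) concentrates in those first components because
#' it is low-rank in time, while decorrelated bubble signal survives.
#'
#' The reconstruction is computed as the projection
#' `X - X V_K V_K*` with `V_K` the top-K eigenvectors of the temporal Gram
#' matrix `X* X` — algebraically identical to zeroing the singular values
#' but avoiding the full left singular basis. Complex input (pre-envelope
#' data) is supported. Blocks are independent and non-overlapping; a
#' trailing remainder of a single frame is merged into the previous block.
#'
#' @param seq a [VolumeSequence-class] (real or complex) with at least 2
#'   frames.
#' @param blockSize frames per filtering block (default 200).
#' @param removedFraction fraction of the block's temporal dimension to
#'   remove, in `[0, 1)` (default 0.15, i.e. 30 components of a 200-frame
#'   block).
#' @return the filtered [VolumeSequence-class]; `removedFraction = 0`
#'   returns the input values unchanged.
#' @export
svdClutterFilter <- function(seq, blockSize = 200L, removedFraction = 0.15) {
  if (blockSize < 2L) stop("blockSize must be >= 2")
  if (removedFraction < 0 || removedFraction >= 1)
    stop("removedFraction must be in [0, 1)")
  nt <- nFrames(seq)
  if (nt < 2L) stop("need at least 2 frames to clutter-filter")
  a <- frameArray(seq)
  d <- dim(a)
  starts <- seq(1L, nt, by = blockSize)
  if (length(starts) > 1L && nt - starts[length(starts)] + 1L < 2L)
    starts <- starts[-length(starts)]
  for (s in starts) {
    e <- if (s == starts[length(starts)]) nt else min(s + blockSize - 1L, nt)
    X <- matrix(a[, , , s:e], nrow = prod(d[1:3]))
    ntB <- ncol(X)
    K <- ceiling(removedFraction * ntB)
    if (K >= 1L) {
      G <- crossprod(Conj(X), X)
      ev <- eigen(G, symmetric = TRUE)
      Vk <- ev$vectors[, seq_len(K), drop = FALSE]
      X <- X - (X %*% Vk) %*% Conj(t(Vk))
      a[, , , s:e] <- array(X, c(d[1:3], ntB))
    }
  }
  volumeSequence(a, imagingGridOf(seq), frameRate(seq))
}
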