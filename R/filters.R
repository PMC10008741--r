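# Shared 3-D array filtering primitives. All separable convolutions use
# symmetric (edge-repeating) reflection at the boundaries.

reflectIdx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

indexAxis3 <- function(a, axis, idx) {
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# 1-D convolution along one axis of a 3-D array, kernel centered.
convolveAxis3 <- function(a, kernel, axis) {
  n <- dim(a)[axis]
  hw <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  base <- seq_len(n)
  for (j in seq_along(kernel)) {
    off <- j - 1L - hw
    out <- out + kernel[j] * indexAxis3(a, axis, reflectIdx(base + off, n))
  }
  out
}

gaussKernel1 <- function(sigma, halfwidth = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(halfwidth)) halfwidth <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-halfwidth, halfwidth))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable anisotropic Gaussian smoothing, sigma per axis in voxels.
gaussSmooth3 <- function(a, sigmaVox, halfwidth = NULL) {
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0)
      a <- convolveAxis3(a, gaussKernel1(sigmaVox[ax], halfwidth[ax]), ax)
  }
  a
}

# Box dilation of the nonzero mask, size^3 neighborhood (separable OR).
dilateNonzero3 <- function(a, size = 3L) {
  hw <- (size - 1L) %/% 2L
  m <- a != 0
  for (ax in 1:3) {
    n <- dim(m)[ax]
    acc <- array(FALSE, dim(m))
    for (off in -hw:hw)
      acc <- acc | indexAxis3(m, ax, pmin(pmax(seq_len(n) + off, 1L), n))
    m <- acc
  }
  m
}

#' 3-D median filter
#'
#' Cubic-kernel median filter with edge-replicating boundaries. When
#' `subset` is supplied (a logical array), the median is evaluated only at
#' those voxels and all others are set to `fill`; [velocityMap()] uses this
#' to skip voxels whose whole neighborhood is zero.
#'
#' @param a 3-D numeric array.
#' @param size odd kernel edge length (default 3).
#' @param subset optional logical array of voxels to evaluate.
#' @param fill value for non-evaluated voxels.
#' @return filtered array, same dims as `a`.
#' @export
medianFilter3 <- function(a, size = 3L, subset = NULL, fill = 0) {
  stopifnot(size %% 2L == 1L)
  d <- dim(a)
  hw <- (size - 1L) %/% 2L
  if (is.null(subset)) {
    idx <- seq_along(a)
    coords <- arrayInd(idx, d)
  } else {
    idx <- which(subset)
    if (!length(idx)) return(array(fill, d))
    coords <- arrayInd(idx, d)
  }
  offs <- as.matrix(expand.grid(dz = -hw:hw, dx = -hw:hw, dy = -hw:hw))
  vals <- matrix(0, length(idx), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    zz <- pmin(pmax(coords[, 1] + offs[j, 1], 1L), d[1])
    xx <- pmin(pmax(coords[, 2] + offs[j, 2], 1L), d[2])
    yy <- pmin(pmax(coords[, 3] + offs[j, 3], 1L), d[3])
    vals[, j] <- a[cbind(zz, xx, yy)]
  }
  med <- apply(vals, 1L, stats::median)
  out <- array(fill, d)
  out[idx] <- med
  out
}
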