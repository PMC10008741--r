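# Independent brute-force oracles used against the package implementations.

# all permutations of 1..n (for assignment enumeration, n <= 5)
permsOf <- function(n) {
  if (n == 1L) return(matrix(1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- permsOf(n - 1L)
    cbind(i, matrix(setdiff(seq_len(n), i)[p], nrow(p)))
  }))
}

# minimum-cost assignment by exhaustive enumeration (Inf -> big penalty)
assignmentOracle <- function(cost) {
  n <- nrow(cost)
  fin <- cost[is.finite(cost)]
  big <- (if (length(fin)) max(abs(fin)) + 1 else 1) * (n + 1)
  a <- cost; a[!is.finite(a)] <- big
  pm <- permsOf(n)
  costs <- apply(pm, 1L, function(p) sum(a[cbind(seq_len(n), p)]))
  list(cost = min(costs), perm = pm[which.min(costs), ])
}

# recursive flood-fill labeling of a 3-D logical mask
floodFillOracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nnz <- rowSums(offs != 0)
  offs <- switch(as.character(connectivity),
                 "6" = offs[nnz == 1, , drop = FALSE],
                 "18" = offs[nnz >= 1 & nnz <= 2, , drop = FALSE],
                 "26" = offs[nnz >= 1, , drop = FALSE])
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(start, d)[1, ])
    labels[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(offs))) {
        q <- p + offs[j, ]
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# direct sliding-window 3-D convolution with reflective boundaries
denseConvOracle <- function(a, kernels) {
  d <- dim(a)
  hw <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, 0L)
  refl <- function(i, n) {
    m <- (i - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (x in seq_len(d[2])) for (y in seq_len(d[3])) {
    s <- 0
    for (a1 in -hw[1]:hw[1]) for (a2 in -hw[2]:hw[2]) for (a3 in -hw[3]:hw[3]) {
      s <- s + kernels[[1]][a1 + hw[1] + 1L] * kernels[[2]][a2 + hw[2] + 1L] *
        kernels[[3]][a3 + hw[3] + 1L] *
        a[refl(z + a1, d[1]), refl(x + a2, d[2]), refl(y + a3, d[3])]
    }
    out[z, x, y] <- s
  }
  out
}

# brute-force 3-D median filter with edge replication
medianOracle <- function(a, size = 3L) {
  d <- dim(a)
  hw <- (size - 1L) %/% 2L
  out <- array(0, d)
  for (z in seq_len(d[1])) for (x in seq_len(d[2])) for (y in seq_len(d[3])) {
    zz <- pmin(pmax(z + (-hw:hw), 1L), d[1])
    xx <- pmin(pmax(x + (-hw:hw), 1L), d[2])
    yy <- pmin(pmax(y + (-hw:hw), 1L), d[3])
    out[z, x, y] <- median(a[zz, xx, yy])
  }
  out
}

# dense line-sampling rasterization oracle
rasterOracle <- function(p0, p1, grid, step) {
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  vox <- round(sweep(sweep(pts, 2, gridOrigin(grid)), 2,
                     gridSpacing(grid), "/") + 1)
  unique(vox)
}
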