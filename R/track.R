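#' Tracking parameters
#'
#' @param maxLinkDistance gate in mm: candidate pairings farther apart than
#'   this are forbidden. Default `NULL` resolves to `vMax / frameRate` when
#'   tracking (the gate is what bounds the maximum detectable speed).
#' @param vMax maximum expected bubble speed in mm/s (default 100), used
#'   only to derive the default gate.
#' @param minTrackLength tracks with fewer positions are discarded
#'   (default 10; a 10-position track is kept, a 9-position track is not).
#' @param sgWindow,sgOrder Savitzky-Golay window (odd) and polynomial
#'   order for coordinate smoothing (defaults 5 and 2).
#' @param useSmoothedVelocities compute per-segment velocities from the
#'   smoothed positions (default) or the raw ones.
#' @param maxTurnAngle,maxAcceleration optional track pruning limits
#'   (degrees per vertex; mm/s^2). Both default to `Inf` — OFF — because
#'   such pruning can erase genuinely tortuous vessels, the very
#'   abnormality many studies look for; see [pruneTracks()].
#' @return list of class `TrackConfig`.
#' @export
trackConfig <- function(maxLinkDistance = NULL, vMax = 100,
                        minTrackLength = 10L, sgWindow = 5L, sgOrder = 2L,
                        useSmoothedVelocities = TRUE,
                        maxTurnAngle = Inf, maxAcceleration = Inf) {
  if (!is.null(maxLinkDistance) && maxLinkDistance <= 0)
    stop("maxLinkDistance must be > 0")
  if (minTrackLength < 2L) stop("minTrackLength must be >= 2")
  if (sgWindow %% 2L == 0L || sgWindow <= sgOrder)
    stop("sgWindow must be odd and greater than sgOrder")
  structure(list(maxLinkDistance = maxLinkDistance, vMax = vMax,
                 minTrackLength = as.integer(minTrackLength),
                 sgWindow = as.integer(sgWindow),
                 sgOrder = as.integer(sgOrder),
                 useSmoothedVelocities = useSmoothedVelocities,
                 maxTurnAngle = maxTurnAngle,
                 maxAcceleration = maxAcceleration),
            class = "TrackConfig")
}

#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' O(n^3) potentials / shortest-augmenting-path method. Infinite entries
#' mark forbidden pairings and are replaced internally by a large finite
#' penalty, so a solution always exists; callers drop penalized pairs.
#'
#' @param cost square numeric matrix; `Inf` allowed.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square")
  if (n == 0L) return(integer(0))
  finite <- cost[is.finite(cost)]
  big <- (if (length(finite)) max(abs(finite)) + 1 else 1) * (n + 1)
  a <- cost
  a[!is.finite(a)] <- big
  u <- numeric(n); v <- numeric(n)
  p <- integer(n + 1L)            # p[j + 1]: row assigned to column j
  way <- integer(n)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- a[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used) - 1L
      u[p[usedCols + 1L]] <- u[p[usedCols + 1L]] + delta
      pos <- usedCols[usedCols > 0L]
      v[pos] <- v[pos] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

#' Link localizations between consecutive frames
#'
#' Minimum-total-Euclidean-distance one-to-one assignment among candidate
#' pairs within the gate (`maxLinkDistance`), solved with the Hungarian
#' algorithm on a square-padded cost matrix. Detections left unassigned
#' start or terminate tracks.
#'
#' @param locsA,locsB matrices (or data.frames) with columns
#'   `z_mm`, `x_mm`, `y_mm` for frames t and t+1.
#' @param maxLinkDistance gate in mm.
#' @return data.frame with columns `i` (row in `locsA`), `j` (row in
#'   `locsB`) and `dist` (mm) for each accepted pair.
#' @export
linkFrames <- function(locsA, locsB, maxLinkDistance) {
  A <- posMatrix(locsA); B <- posMatrix(locsB)
  nA <- nrow(A); nB <- nrow(B)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (nA == 0L || nB == 0L) return(empty)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  dist <- sqrt(pmax(d2, 0))
  cost <- dist
  cost[cost > maxLinkDistance] <- Inf
  if (!any(is.finite(cost))) return(empty)
  n <- max(nA, nB)
  sq <- matrix(Inf, n, n)
  sq[seq_len(nA), seq_len(nB)] <- cost
  assign <- solveAssignment(sq)
  i <- seq_len(nA)
  j <- assign[i]
  ok <- j <= nB & is.finite(cost[cbind(i, pmin(j, nB))])
  data.frame(i = i[ok], j = j[ok], dist = dist[cbind(i[ok], j[ok])])
}

posMatrix <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("z_mm", "x_mm", "y_mm")])
  else rbindable(x)
}

#' Assemble tracks from per-frame localizations
#'
#' Frame-to-frame Hungarian linking with no gap closing: a localization
#' with no accepted pairing in the next frame terminates its track, and
#' unmatched localizations start new tracks. Frames within a track are
#' strictly consecutive.
#'
#' @param locs data.frame from [localizePass()] (one pass).
#' @param frameRate volumes/s (used to resolve the default gate).
#' @param config a [trackConfig()].
#' @return data.frame with `track_id`, `frame`, `z_mm`, `x_mm`, `y_mm`.
#' @export
buildTracks <- function(locs, frameRate, config = trackConfig()) {
  gate <- config$maxLinkDistance %||% (config$vMax / frameRate)
  cols <- c("frame", "z_mm", "x_mm", "y_mm")
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      z_mm = numeric(0), x_mm = numeric(0), y_mm = numeric(0))
  if (nrow(locs) == 0L) return(empty)
  locs <- locs[order(locs$frame), cols]
  frames <- min(locs$frame):max(locs$frame)
  byFrame <- split(locs, factor(locs$frame, levels = frames))
  nextId <- 0L
  rows <- list()
  prev <- byFrame[[1]]
  prevIds <- integer(nrow(prev))
  if (nrow(prev)) {
    prevIds <- nextId + seq_len(nrow(prev))
    nextId <- nextId + nrow(prev)
    rows[[1]] <- cbind(track_id = prevIds, prev)
  }
  for (k in seq_along(frames)[-1]) {
    cur <- byFrame[[k]]
    curIds <- integer(nrow(cur))
    if (nrow(cur)) {
      if (nrow(prev)) {
        pairs <- linkFrames(prev, cur, gate)
        curIds[pairs$j] <- prevIds[pairs$i]
      }
      new <- curIds == 0L
      if (any(new)) {
        curIds[new] <- nextId + seq_len(sum(new))
        nextId <- nextId + sum(new)
      }
      rows[[k]] <- cbind(track_id = curIds, cur)
    }
    prev <- cur
    prevIds <- curIds
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Discard short tracks
#'
#' @param tracks data.frame with a `track_id` column.
#' @param minTrackLength tracks with fewer positions are removed; a track
#'   of exactly `minTrackLength` positions is kept.
#' @return filtered data.frame.
#' @export
filterTracks <- function(tracks, minTrackLength = 10L) {
  if (nrow(tracks) == 0L) return(tracks)
  n <- table(tracks$track_id)
  keep <- names(n)[n >= minTrackLength]
  out <- tracks[tracks$track_id %in% as.integer(keep), ]
  rownames(out) <- NULL
  out
}

#' Savitzky-Golay smoothing of track coordinates
#'
#' Each coordinate of each track is filtered independently with
#' `signal::sgolayfilt`; tracks shorter than the window pass through
#' unsmoothed. A polynomial trajectory of degree `<= sgOrder` is
#' reproduced exactly.
#'
#' @param tracks data.frame from [buildTracks()].
#' @param sgWindow odd window length.
#' @param sgOrder polynomial order, `< sgWindow`.
#' @return `tracks` with added `z_sm`, `x_sm`, `y_sm` columns.
#' @export
smoothTracks <- function(tracks, sgWindow = 5L, sgOrder = 2L) {
  tracks$z_sm <- tracks$z_mm
  tracks$x_sm <- tracks$x_mm
  tracks$y_sm <- tracks$y_mm
  if (nrow(tracks) == 0L) return(tracks)
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    if (length(sel) < sgWindow) next
    for (cc in c("z", "x", "y"))
      tracks[sel, paste0(cc, "_sm")] <-
        signal::sgolayfilt(tracks[sel, paste0(cc, "_mm")],
                           p = sgOrder, n = sgWindow)
  }
  tracks
}

#' Per-segment track velocities
#'
#' Segment speed is the Euclidean distance between consecutive track
#' positions times the frame rate; the signed axial component uses the z
#' displacement alone. Values are stored on the first row of each segment;
#' the last row of a track carries `NA`.
#'
#' @param tracks data.frame with (smoothed) positions.
#' @param frameRate volumes/s.
#' @param useSmoothed use `*_sm` columns when present (default TRUE).
#' @return `tracks` with added `speed_mm_s` and `vz_mm_s` columns.
#' @export
trackVelocities <- function(tracks, frameRate, useSmoothed = TRUE) {
  tracks$speed_mm_s <- NA_real_
  tracks$vz_mm_s <- NA_real_
  if (nrow(tracks) == 0L) return(tracks)
  suf <- if (useSmoothed && "z_sm" %in% names(tracks)) "_sm" else "_mm"
  for (id in unique(tracks$track_id)) {
    sel <- which(tracks$track_id == id)
    if (length(sel) < 2L) next
    p <- as.matrix(tracks[sel, paste0(c("z", "x", "y"), suf)])
    dp <- diff(p)
    tracks$speed_mm_s[sel[-length(sel)]] <- sqrt(rowSums(dp^2)) * frameRate
    tracks$vz_mm_s[sel[-length(sel)]] <- dp[, 1] * frameRate
  }
  tracks
}

#' Prune implausibly kinked or jerky tracks
#'
#' Removes whole tracks containing any vertex whose turning angle (between
#' consecutive raw segment directions) exceeds `maxTurnAngle` degrees or
#' whose acceleration (change of segment velocity times the frame rate)
#' exceeds `maxAcceleration` mm/s^2. OFF (`Inf`) by default: kink-based
#' pruning can erase genuinely tortuous vessels, so enabling it is an
#' explicit analysis decision.
#'
#' @param tracks data.frame from [buildTracks()].
#' @param frameRate volumes/s.
#' @param maxTurnAngle degrees per vertex.
#' @param maxAcceleration mm/s^2.
#' @return filtered data.frame.
#' @export
pruneTracks <- function(tracks, frameRate, maxTurnAngle = Inf,
                        maxAcceleration = Inf) {
  if (nrow(tracks) == 0L || (!is.finite(maxTurnAngle) &&
                             !is.finite(maxAcceleration)))
    return(tracks)
  drop <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(sel) {
    p <- as.matrix(tracks[sel, c("z_mm", "x_mm", "y_mm")])
    if (nrow(p) < 3L) return(FALSE)
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    ok <- len > 0
    ang <- rep(0, nrow(d) - 1L)
    for (i in seq_len(nrow(d) - 1L)) {
      if (!ok[i] || !ok[i + 1L]) next
      cosang <- sum(d[i, ] * d[i + 1L, ]) / (len[i] * len[i + 1L])
      ang[i] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    acc <- sqrt(rowSums((diff(d) * frameRate)^2)) * frameRate
    any(ang > maxTurnAngle) || any(acc > maxAcceleration)
  }, TRUE)
  keep <- names(drop)[!drop]
  out <- tracks[tracks$track_id %in% as.integer(keep), ]
  rownames(out) <- NULL
  out
}

#' Localizations to finished tracks
#'
#' Convenience wrapper: [buildTracks()], [filterTracks()],
#' [smoothTracks()], [trackVelocities()] in the standard order.
#'
#' @inheritParams buildTracks
#' @return data.frame with raw and smoothed positions and per-segment
#'   velocities.
#' @export
trackLocalizations <- function(locs, frameRate, config = trackConfig()) {
  t <- buildTracks(locs, frameRate, config)
  t <- filterTracks(t, config$minTrackLength)
  t <- pruneTracks(t, frameRate, config$maxTurnAngle, config$maxAcceleration)
  t <- smoothTracks(t, config$sgWindow, config$sgOrder)
  trackVelocities(t, frameRate, config$useSmoothedVelocities)
}
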