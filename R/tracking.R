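## Gated global-nearest-neighbour tracker with constant-velocity prediction:
## a simplified, contract-compatible stand-in for offline multiple-hypothesis
## tracking. Per frame, gated track-detection pairs are assigned globally by
## the Hungarian algorithm; unmatched detections seed new tracks; tracks
## missing longer than maxGap frames are closed.

#' Tracking parameters
#'
#' @param vMax maximum expected cell speed, um/s (sets the gate radius).
#' @param slack additive gate slack, um.
#' @param maxGap maximum number of consecutive missed frames bridged.
#' @param minTrackLength minimum number of points for a track to be kept.
#' @param kVelocity number of trailing steps averaged for the velocity
#'   estimate used in prediction.
#' @param areaWeight lambda for the optional area-similarity cost term
#'   lambda * |dA|/A (0 disables it).
#' @return list of class \code{"TrackingParams"}.
#' @export
trackingParams <- function(vMax = 100, slack = 2, maxGap = 2L,
                           minTrackLength = 10L, kVelocity = 3L,
                           areaWeight = 0) {
  .checkPositive(vMax, "vMax")
  structure(as.list(environment()), class = "TrackingParams")
}

#' Predict the next position of a track
#'
#' Constant-velocity extrapolation using the average velocity over the last
#' \code{k} steps; a single-point track predicts its last position.
#'
#' @param points matrix or data.frame with columns t_s, x_um, y_um (time
#'   ordered).
#' @param dt lookahead time, s.
#' @param k number of trailing steps to average.
#' @param vMax,slack gate parameters (see \code{\link{trackingParams}}).
#' @return list(position = c(x, y) um, gate = radius um).
#' @export
predictPosition <- function(points, dt, k = 3L, vMax = 100, slack = 2) {
  points <- as.data.frame(points)
  np <- nrow(points)
  .stopIfNot(np >= 1L, "track must have at least one point")
  last <- c(points$x_um[np], points$y_um[np])
  gate <- vMax * dt + slack
  if (np == 1L) return(list(position = last, gate = gate))
  i0 <- max(1L, np - k)
  dtk <- points$t_s[np] - points$t_s[i0]
  vel <- if (dtk > 0)
    c(points$x_um[np] - points$x_um[i0],
      points$y_um[np] - points$y_um[i0]) / dtk else c(0, 0)
  list(position = last + vel * dt, gate = gate)
}

## Internal tracker state: a list of track records
##   list(id, points = data.frame(frame, t_s, x_um, y_um, area_um2),
##        missed = 0L, open = TRUE)

#' Link one frame of detections into active tracks
#'
#' Gated globally optimal one-to-one assignment of active tracks to
#' detections by distance from the constant-velocity prediction (plus an
#' optional area-similarity term). Exposed mainly for inspection and tests;
#' \code{\link{buildTracks}} drives the full pass.
#'
#' @param state list of active track records (see \code{\link{buildTracks}}).
#' @param detections data.frame(frame, t_s, x_um, y_um, area_um2) of one
#'   frame.
#' @param params \code{\link{trackingParams}}.
#' @param nextId next fresh track id.
#' @return list(state, nextId).
#' @export
linkFrame <- function(state, detections, params = trackingParams(),
                      nextId = 1L) {
  nd <- nrow(detections)
  active <- which(vapply(state, function(s) s$open, logical(1)))
  na <- length(active)
  BIG <- 1e8
  assigned <- integer(0)
  if (na > 0L && nd > 0L) {
    cost <- matrix(BIG, na, nd)
    for (a in seq_len(na)) {
      tr <- state[[active[a]]]
      dt <- detections$t_s[1] - tr$points$t_s[nrow(tr$points)]
      pr <- predictPosition(tr$points, dt, params$kVelocity, params$vMax,
                            params$slack)
      d <- sqrt((detections$x_um - pr$position[1])^2 +
                (detections$y_um - pr$position[2])^2)
      cst <- d
      if (params$areaWeight > 0) {
        aLast <- tr$points$area_um2[nrow(tr$points)]
        cst <- cst + params$areaWeight *
          abs(detections$area_um2 - aLast) / pmax(aLast, 1e-9)
      }
      cst[d > pr$gate] <- BIG
      cost[a, ] <- cst
    }
    if (na <= nd) {
      sol <- solveAssignment(cost)
      pairs <- cbind(seq_len(na), sol)
    } else {
      sol <- solveAssignment(t(cost))
      pairs <- cbind(sol, seq_len(nd))
    }
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; j <- pairs[p, 2]
      if (a == 0L || j == 0L || cost[a, j] >= BIG) next
      tr <- state[[active[a]]]
      tr$points <- rbind(tr$points, detections[j, , drop = FALSE])
      tr$missed <- 0L
      state[[active[a]]] <- tr
      assigned <- c(assigned, j)
    }
  }
  ## unmatched active tracks age and eventually close
  matchedTracks <- if (length(assigned) && na > 0L)
    active[vapply(seq_len(na), function(a) {
      tr <- state[[active[a]]]
      tr$points$frame[nrow(tr$points)] == detections$frame[1]
    }, logical(1))] else integer(0)
  for (ia in active) {
    if (ia %in% matchedTracks) next
    tr <- state[[ia]]
    tr$missed <- tr$missed + 1L
    if (tr$missed > params$maxGap) tr$open <- FALSE
    state[[ia]] <- tr
  }
  ## unmatched detections seed new tracks
  newIdx <- setdiff(seq_len(nd), assigned)
  for (j in newIdx) {
    state[[length(state) + 1L]] <- list(
      id = nextId, points = detections[j, , drop = FALSE],
      missed = 0L, open = TRUE)
    nextId <- nextId + 1L
  }
  list(state = state, nextId = nextId)
}

#' Build tracks from per-frame detections
#'
#' Full tracking pass over a detection table; converts pixel coordinates to
#' micrometres (y kept in image orientation times pixel scale), links frames,
#' and drops tracks shorter than \code{minTrackLength}.
#'
#' @param detections data.frame(frame, x_px, y_px, area_px2) as produced by
#'   \code{\link{detectStack}} (0-based frames).
#' @param fps frame rate, Hz.
#' @param pixelSize pixel scale, um/px.
#' @param params \code{\link{trackingParams}}.
#' @return A \linkS4class{TrackSet} (positions in um).
#' @export
buildTracks <- function(detections, fps, pixelSize,
                        params = trackingParams()) {
  .checkPositive(fps, "fps")
  .checkPositive(pixelSize, "pixelSize")
  empty <- trackSet(data.frame(track_id = integer(0), frame = integer(0),
                               t_s = numeric(0), x_um = numeric(0),
                               y_um = numeric(0), area_um2 = numeric(0)),
                    pixelSize = pixelSize, frameRate = fps)
  if (is.null(detections) || !nrow(detections)) return(empty)
  d <- data.frame(frame = detections$frame,
                  t_s = detections$frame / fps,
                  x_um = detections$x_px * pixelSize,
                  y_um = detections$y_px * pixelSize,
                  area_um2 = detections$area_px2 * pixelSize^2)
  d <- d[order(d$frame), , drop = FALSE]
  state <- list()
  nextId <- 1L
  ## iterate over the full frame range so tracks age on empty frames too
  for (f in min(d$frame):max(d$frame)) {
    res <- linkFrame(state, d[d$frame == f, , drop = FALSE], params, nextId)
    state <- res$state
    nextId <- res$nextId
  }
  keep <- Filter(function(s) nrow(s$points) >= params$minTrackLength, state)
  if (!length(keep)) return(empty)
  rows <- do.call(rbind, lapply(keep, function(s)
    cbind(track_id = s$id, s$points)))
  trackSet(rows, pixelSize = pixelSize, frameRate = fps)
}

#' Association accuracy against ground truth
#'
#' Matches each estimated track point to the nearest ground-truth detection
#' in its frame (within \code{maxDist}) and reports the fraction of
#' consecutive point pairs within estimated tracks whose matched true ids
#' agree -- the link-level association accuracy.
#'
#' @param tracks a \linkS4class{TrackSet} (um coordinates).
#' @param truth data.frame(frame, cell_id, x_px, y_px) ground-truth table.
#' @param pixelSize pixel scale, um/px, to place truth in um.
#' @param maxDist matching gate, um.
#' @return list(accuracy, nLinks, nTracks).
#' @export
associationAccuracy <- function(tracks, truth, pixelSize, maxDist = 2) {
  d <- trackData(tracks)
  if (!nrow(d)) return(list(accuracy = NA_real_, nLinks = 0L, nTracks = 0L))
  tid <- rep(NA_integer_, nrow(d))
  for (f in unique(d$frame)) {
    sel <- which(d$frame == f)
    tt <- truth[truth$frame == f, ]
    if (!nrow(tt)) next
    for (i in sel) {
      dist <- sqrt((tt$x_px * pixelSize - d$x_um[i])^2 +
                   (tt$y_px * pixelSize - d$y_um[i])^2)
      j <- which.min(dist)
      if (dist[j] <= maxDist) tid[i] <- tt$cell_id[j]
    }
  }
  good <- 0L; total <- 0L
  for (id in unique(d$track_id)) {
    sel <- which(d$track_id == id)
    ids <- tid[sel]
    n <- length(ids)
    if (n < 2L) next
    total <- total + n - 1L
    good <- good + sum(!is.na(ids[-1]) & !is.na(ids[-n]) &
                       ids[-1] == ids[-n])
  }
  list(accuracy = if (total) good / total else NA_real_,
       nLinks = total, nTracks = nTracks(tracks))
}
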