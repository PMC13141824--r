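## U-turn magnetometry: decompose square-wave-field tracks into per-reversal
## U-turn segments, map each to a canonical frame, fit the theoretical shape
## y = -(L/pi) ln sec(pi x / L), and invert the width for the magnetic
## moment m = pi alpha v / (B L).

#' U-turn analysis parameters
#'
#' @param minPoints minimum points per U-turn segment.
#' @param settleDeg segment end: heading settled within this many degrees of
#'   the new field direction.
#' @param residualThreshold maximum normalised RMS misfit for an eligible
#'   fit.
#' @param spanTolerance maximum relative mismatch between the observed
#'   leg-to-leg x-span and the fitted width L; a fully developed U-turn has
#'   span close to L, while non-U-turn shapes (e.g. circular arcs) fit with
#'   widths inconsistent with their span.
#' @param maxWidth maximum plausible L, um (e.g. the field-of-view
#'   diagonal); Inf disables the check.
#' @param preContext number of pre-reversal steps used for the incoming
#'   heading estimate.
#' @param aggregate \code{"mean"} or \code{"median"} across a track's
#'   eligible U-turns.
#' @return list of class \code{"UTurnParams"}.
#' @export
uturnParams <- function(minPoints = 10L, settleDeg = 5,
                        residualThreshold = 0.05, spanTolerance = 0.2,
                        maxWidth = Inf, preContext = 5L,
                        aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  structure(as.list(environment()), class = "UTurnParams")
}

## Per-step heading angles of a track (forward differences, n-1 values).
.stepHeadings <- function(d) {
  atan2(diff(d$y_um), diff(d$x_um))
}

#' Segment a track into U-turn candidates
#'
#' One candidate per field reversal, spanning from the reversal time to the
#' earlier of the next reversal and the moment the (smoothed) heading has
#' settled within \code{settleDeg} of the new field direction. A few
#' pre-reversal steps are attached as attribute \code{"preHeading"} for
#' canonical alignment. With no protocol (\code{field = NULL}) reversals are
#' detected from sign changes of the smoothed velocity component along the
#' track's principal axis.
#'
#' @param track data.frame of one track (frame, t_s, x_um, y_um, ...).
#' @param field a square-wave \linkS4class{FieldProtocol}, or NULL for
#'   heading-based fallback detection.
#' @param params \code{\link{uturnParams}}.
#' @return list of segment data.frames (possibly empty), each with
#'   attributes preHeading (rad) and reversalTime (s).
#' @export
segmentUturns <- function(track, field = NULL, params = uturnParams()) {
  track <- as.data.frame(track)
  n <- nrow(track)
  if (n < 3L) return(list())
  if (!is.null(field)) {
    stopifnot(is(field, "FieldProtocol"))
    if (field@mode != "square_wave") return(list())
    revTimes <- field@reversalTimes
    revTimes <- revTimes[revTimes > min(track$t_s) & revTimes < max(track$t_s)]
    newDir <- lapply(revTimes, function(rt) fieldDirection(field, rt)[1, ])
  } else {
    ## fallback: detect heading reversals along the dominant axis
    hd <- .stepHeadings(track)
    xy <- cbind(track$x_um, track$y_um)
    pc <- stats::prcomp(xy)$rotation[, 1]
    proj <- cos(hd) * pc[1] + sin(hd) * pc[2]
    k <- min(5L, max(1L, floor(length(proj) / 4)))
    sm <- stats::filter(proj, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- proj[is.na(sm)]
    sgn <- sign(sm)
    flips <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    ## post-reversal direction: the settled heading in the middle of the
    ## interval between this crossing and the next (just after a crossing
    ## the heading is still turning; just before the next one the following
    ## turn may already have begun)
    bounds <- c(flips, length(hd))
    newDir <- lapply(seq_along(flips), function(i) {
      j1 <- flips[i]; j2 <- bounds[i + 1L]
      lo <- j1 + max(1L, floor(0.3 * (j2 - j1)))
      hi <- j1 + max(1L, floor(0.7 * (j2 - j1)))
      ang <- atan2(mean(sin(hd[lo:hi])), mean(cos(hd[lo:hi])))
      c(cos(ang), sin(ang))
    })
    ## the crossing lags the actual reversal: backtrack to where the
    ## heading still matched the old (anti-parallel) settled direction, so
    ## the segment keeps its entry leg
    settleRad0 <- params$settleDeg * pi / 180
    starts <- vapply(seq_along(flips), function(i) {
      oldAng <- atan2(-newDir[[i]][2], -newDir[[i]][1])
      j <- flips[i]
      while (j > 1L && abs(.wrapAngle(hd[j - 1L] - oldAng)) > settleRad0)
        j <- j - 1L
      j
    }, integer(1))
    revTimes <- track$t_s[starts]
  }
  if (!length(revTimes)) return(list())

  segs <- list()
  settleRad <- params$settleDeg * pi / 180
  for (i in seq_along(revTimes)) {
    rt <- revTimes[i]
    tEnd <- if (i < length(revTimes)) revTimes[i + 1] else max(track$t_s) + 1
    idx <- which(track$t_s >= rt & track$t_s < tEnd)
    if (length(idx) < 3L) next
    ## settled: smoothed step heading within settleDeg of the new direction
    hd <- .stepHeadings(track[idx, ])
    target <- atan2(newDir[[i]][2], newDir[[i]][1])
    dev <- abs(.wrapAngle(hd - target))
    if (min(dev) > pi / 2) next   # no heading reversal response (e.g. m = 0)
    settled <- which(dev < settleRad)
    ## keep the turn through the first settled step
    cut <- if (length(settled)) settled[1] + 1L else length(idx)
    idx <- idx[seq_len(min(length(idx), max(cut, 3L)))]
    if (length(idx) < params$minPoints) next
    pre <- which(track$t_s < rt)
    if (length(pre) < 2L) next
    pre <- pre[max(1L, length(pre) - params$preContext):length(pre)]
    preHd <- atan2(track$y_um[pre[length(pre)]] - track$y_um[pre[1]],
                   track$x_um[pre[length(pre)]] - track$x_um[pre[1]])
    seg <- track[idx, , drop = FALSE]
    attr(seg, "preHeading") <- preHd
    attr(seg, "reversalTime") <- rt
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

#' Map a U-turn segment to its canonical frame
#'
#' Rotates the segment so the pre-reversal mean heading points along +y and
#' translates the turning apex (maximal y) to the origin; the canonical
#' points then follow y = -(L/pi) ln sec(pi x / L) for an ideal turn. The
#' construction is invariant under rigid motions of the input.
#'
#' @param segment a segment from \code{\link{segmentUturns}} (attribute
#'   \code{"preHeading"} required unless given via \code{preHeading}).
#' @param preHeading pre-reversal heading in rad (overrides the attribute).
#' @return n x 2 matrix of canonical (x, y) in um, or NULL for degenerate
#'   (zero-extent) segments.
#' @export
canonicalizeSegment <- function(segment, preHeading = NULL) {
  if (is.null(preHeading)) preHeading <- attr(segment, "preHeading")
  .stopIfNot(!is.null(preHeading), "preHeading required")
  xy <- cbind(segment$x_um, segment$y_um)
  if (nrow(xy) < 3L || max(apply(xy, 2, function(z) diff(range(z)))) < 1e-9)
    return(NULL)
  ## rotate preHeading -> +y: rotation by (pi/2 - preHeading)
  a <- pi / 2 - preHeading
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  can <- xy %*% t(Rm)
  apex <- which.max(can[, 2])
  ## sub-step apex: parabola through the points around the sampled maximum
  ctr <- can[apex, ]
  lo <- max(1L, apex - 2L); hi <- min(nrow(can), apex + 2L)
  if (hi - lo >= 2L) {
    px <- can[lo:hi, 1]; py <- can[lo:hi, 2]
    cf <- tryCatch(stats::lm.fit(cbind(1, px, px^2), py)$coefficients,
                   error = function(e) NULL)
    if (!is.null(cf) && is.finite(cf[3]) && cf[3] < 0) {
      xv <- -cf[2] / (2 * cf[3])
      if (xv > min(px) && xv < max(px))
        ctr <- c(xv, cf[1] + cf[2] * xv + cf[3] * xv^2)
    }
  }
  can <- sweep(can, 2, ctr)
  colnames(can) <- c("x", "y")
  can
}

#' Fit the theoretical U-turn shape
#'
#' Nonlinear least squares of canonical points against
#' y = y0 - (L/pi) ln sec(pi (x - x0) / L) over (L, x0, y0), by Nelder-Mead
#' with a domain penalty (|x - x0| must stay below L/2). Residuals in y are
#' weighted by cos^2 of the local slope angle, i.e. the squared
#' perpendicular distance to the curve is minimised to first order --
#' without this, the steep legs amplify centroid noise without bound. The
#' reported residual is the weighted RMS misfit normalised by L. Initial L
#' is the observed x-extent. The fit is rejected (not an error) when it
#' fails to converge, the normalised residual exceeds the threshold, or L
#' exceeds \code{maxWidth}.
#'
#' @param points canonical n x 2 matrix from
#'   \code{\link{canonicalizeSegment}}.
#' @param params \code{\link{uturnParams}}.
#' @param speed optional mean segment speed to carry along, um/s.
#' @return A \linkS4class{UTurnFit}; slot \code{converged} flags
#'   eligibility.
#' @export
fitUturnWidth <- function(points, params = uturnParams(), speed = NA_real_) {
  reject <- function(L = NA_real_, res = Inf, n = 0L)
    new("UTurnFit", width = if (is.na(L)) 1e-12 else L,
        points = if (is.null(points)) matrix(0, 0, 2) else points,
        residual = res, nPoints = as.integer(n), converged = FALSE,
        speed = speed)
  if (is.null(points) || nrow(points) < 3L) return(reject())
  x <- points[, 1]; y <- points[, 2]
  n <- length(x)
  extent <- diff(range(x))
  if (extent < 1e-9) return(reject(n = n))

  wrss <- function(p, detail = FALSE) {
    L <- p[1]; x0 <- p[2]; y0 <- p[3]
    u <- pi * (x - x0) / L
    if (L <= 0 || any(abs(u) >= pi / 2 * 0.999999))
      return(1e6 * (1 + sum(pmax(abs(u) - pi / 2, 0))))
    yy <- y0 - (L / pi) * log(1 / cos(u))
    w <- cos(u)^2   # slope weight: w * r^2 is the squared normal distance
    if (detail) return(list(rss = sum(w * (y - yy)^2), wsum = sum(w)))
    sum(w * (y - yy)^2)
  }
  best <- NULL
  for (f in c(1.05, 1.2, 1.6, 2.5)) {
    st <- c(extent * f, mean(range(x)), 0)
    op <- stats::optim(st, wrss, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  L <- best$par[1]
  det <- wrss(best$par, detail = TRUE)
  ## RMS perpendicular distance to the fitted curve, normalised by L
  resid <- if (is.list(det)) sqrt(det$rss / n) / L else Inf
  spanMismatch <- abs(extent - L) / L
  conv <- best$convergence == 0 && is.finite(resid) &&
    resid <= params$residualThreshold && L <= params$maxWidth &&
    spanMismatch <= params$spanTolerance
  new("UTurnFit", width = L, points = points, residual = resid,
      nPoints = as.integer(n), converged = conv, speed = speed)
}

#' Estimate per-track magnetic moments
#'
#' Runs the full U-turn chain for every track: segmentation per field
#' reversal, canonical alignment, shape fitting, and the Bean-model moment
#' formula m = pi alpha v / (B L) per eligible U-turn, with the per-segment
#' mean speed as v and the trajectory-average effective radius as R. The
#' track moment aggregates eligible U-turns (mean by default). Tracks with
#' no eligible U-turn are excluded with reason "non-magnetic or unfit".
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param field a square-wave \linkS4class{FieldProtocol}.
#' @param medium a \linkS4class{MediumParams}.
#' @param params \code{\link{uturnParams}}.
#' @param convention drag convention, see \code{\link{rotationalDrag}}.
#' @return A \linkS4class{MomentEstimates}.
#' @examples
#' fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4))
#' cs <- cellState(moment = 1.5e-15, speed = 25, radius = 0.7)
#' tr <- simulateTrajectory(cs, fp, dt = 0.01, duration = 6)
#' estimateMoments(tr, fp)
#' @export
estimateMoments <- function(tracks, field, medium = mediumParams(),
                            params = uturnParams(),
                            convention = c("pisq", "sphere")) {
  stopifnot(is(tracks, "TrackSet"), is(field, "FieldProtocol"))
  convention <- match.arg(convention)
  d <- trackData(tracks)
  est <- list(); exc <- list()
  for (id in trackIds(tracks)) {
    tr <- d[d$track_id == id, , drop = FALSE]
    Rtrack <- effectiveRadius(mean(tr$area_um2))
    segs <- segmentUturns(tr, field, params)
    ms <- numeric(0); Ls <- numeric(0); vs <- numeric(0)
    for (seg in segs) {
      can <- canonicalizeSegment(seg)
      if (is.null(can)) next
      step <- sqrt(diff(seg$x_um)^2 + diff(seg$y_um)^2)
      vseg <- sum(step) / (seg$t_s[nrow(seg)] - seg$t_s[1])
      fit <- fitUturnWidth(can, params, speed = vseg)
      if (!fit@converged) next
      Ls <- c(Ls, fit@width)
      vs <- c(vs, vseg)
      ms <- c(ms, momentFromUturn(fit@width, vseg, Rtrack,
                                  B = field@magnitude,
                                  eta = medium@viscosity,
                                  convention = convention))
    }
    if (!length(ms)) {
      exc[[length(exc) + 1L]] <- data.frame(track_id = id,
                                            reason = "non-magnetic or unfit")
      next
    }
    agg <- if (params$aggregate == "mean") mean else stats::median
    est[[length(est) + 1L]] <- data.frame(
      track_id = id, R_um = Rtrack, v_um_s = agg(vs),
      alpha = rotationalDrag(Rtrack, medium@viscosity, convention),
      m_Am2 = agg(ms), L_um = agg(Ls), n_uturns = length(ms))
  }
  new("MomentEstimates",
      estimates = if (length(est)) do.call(rbind, est) else
        data.frame(track_id = integer(0), R_um = numeric(0),
                   v_um_s = numeric(0), alpha = numeric(0),
                   m_Am2 = numeric(0), L_um = numeric(0),
                   n_uturns = integer(0)),
      excluded = if (length(exc)) do.call(rbind, exc) else
        data.frame(track_id = integer(0), reason = character(0)),
      field = field)
}
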