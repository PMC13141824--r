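## Velocity and radius statistics from reconstructed tracks: central-
## difference speeds, Freedman-Diaconis binning, joint (R, log10 v)
## relative-frequency histograms, and optional filtering of tracks that do
## not comply with the applied field direction.

#' Per-step speeds of a track
#'
#' Central-difference speeds at interior points using frame timestamps:
#' v_i = |p_(i+1) - p_(i-1)| / (t_(i+1) - t_(i-1)), in um/s. A track of
#' length < 3 yields an empty vector.
#'
#' @param track data.frame of one track with t_s, x_um, y_um.
#' @return Numeric vector of length max(0, n - 2).
#' @export
trackVelocities <- function(track) {
  track <- as.data.frame(track)
  n <- nrow(track)
  if (n < 3L) return(numeric(0))
  i <- 2:(n - 1)
  dx <- track$x_um[i + 1] - track$x_um[i - 1]
  dy <- track$y_um[i + 1] - track$y_um[i - 1]
  dt <- track$t_s[i + 1] - track$t_s[i - 1]
  sqrt(dx^2 + dy^2) / dt
}

#' Per-step velocimetry samples for a track set
#'
#' Pairs each interior-point speed with the track's trajectory-average
#' effective radius.
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @return data.frame(track_id, R_um, v_um_s, log10_v).
#' @export
velocimetrySamples <- function(tracks) {
  stopifnot(is(tracks, "TrackSet"))
  d <- trackData(tracks)
  out <- lapply(trackIds(tracks), function(id) {
    tr <- d[d$track_id == id, , drop = FALSE]
    v <- trackVelocities(tr)
    if (!length(v)) return(NULL)
    data.frame(track_id = id, R_um = effectiveRadius(mean(tr$area_um2)),
               v_um_s = v)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(track_id = integer(0), R_um = numeric(0),
                      v_um_s = numeric(0))
  res$log10_v <- ifelse(res$v_um_s > 0, log10(res$v_um_s), NA_real_)
  res
}

#' Freedman-Diaconis bin width
#'
#' width = 2 IQR(x) n^(-1/3); falls back to the Sturges-derived width (range
#' over ceiling(log2 n) + 1 bins) with a warning when the IQR is zero.
#'
#' @param x numeric samples (n >= 2).
#' @return Bin width.
#' @examples
#' fdBinWidth(seq(0, 1, length.out = 1000))
#' @export
fdBinWidth <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  .stopIfNot(n >= 2L, "need at least two finite samples")
  iqr <- stats::IQR(x)
  if (iqr <= 0) {
    warning("zero IQR; falling back to Sturges binning")
    rg <- diff(range(x))
    if (rg <= 0) return(1)
    return(rg / (ceiling(log2(n)) + 1))
  }
  2 * iqr * n^(-1 / 3)
}

#' Joint relative-frequency histogram
#'
#' 2D histogram of (radius, velocity) samples with Freedman-Diaconis bins on
#' each axis and counts normalised to relative frequencies summing to 1.
#' The velocity axis is log10-scaled by default.
#'
#' @param samples data.frame with R_um and v_um_s (as from
#'   \code{\link{velocimetrySamples}}), or a 2-column matrix taken as the
#'   axes directly.
#' @param log10Velocity log10-transform the velocity axis.
#' @return list(xBreaks, yBreaks, xMid, yMid, freq) with sum(freq) == 1;
#'   x is radius, y velocity.
#' @export
jointHistogram <- function(samples, log10Velocity = TRUE) {
  if (is.matrix(samples)) {
    x <- samples[, 1]; y <- samples[, 2]
  } else {
    x <- samples$R_um
    y <- samples$v_um_s
    if (log10Velocity) {
      keep <- y > 0
      x <- x[keep]; y <- log10(y[keep])
    }
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  .stopIfNot(length(x) >= 2L, "need at least two samples per axis")
  bw <- c(fdBinWidth(x), fdBinWidth(y))
  mkBreaks <- function(z, w) {
    lo <- min(z) - w / 2
    k <- max(1L, ceiling((max(z) - lo) / w))
    lo + (0:k) * w
  }
  xb <- mkBreaks(x, bw[1]); yb <- mkBreaks(y, bw[2])
  xi <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  freq <- matrix(0, length(xb) - 1L, length(yb) - 1L)
  for (k in seq_along(xi))
    freq[xi[k], yi[k]] <- freq[xi[k], yi[k]] + 1
  freq <- freq / sum(freq)
  list(xBreaks = xb, yBreaks = yb,
       xMid = (xb[-1] + xb[-length(xb)]) / 2,
       yMid = (yb[-1] + yb[-length(yb)]) / 2, freq = freq)
}

#' Filter tracks by field-direction compliance
#'
#' Keeps tracks whose net displacement direction lies within
#' \code{toleranceDeg} of the given direction (pass the reversed field axis:
#' the direction cells swim after the guiding field is flipped). This
#' filter is OFF by default throughout the pipeline; velocimetry statistics
#' include all detected motion unless it is requested explicitly.
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param axis field axis as a 2-vector.
#' @param toleranceDeg angular tolerance in degrees.
#' @return A \linkS4class{TrackSet} containing the compliant subset.
#' @export
mfComplianceFilter <- function(tracks, axis = c(1, 0), toleranceDeg = 30) {
  stopifnot(is(tracks, "TrackSet"))
  d <- trackData(tracks)
  axis <- axis / sqrt(sum(axis^2))
  tol <- toleranceDeg * pi / 180
  keepIds <- Filter(function(id) {
    tr <- d[d$track_id == id, ]
    net <- c(tr$x_um[nrow(tr)] - tr$x_um[1], tr$y_um[nrow(tr)] - tr$y_um[1])
    nn <- sqrt(sum(net^2))
    if (nn == 0) return(FALSE)
    ang <- acos(pmin(pmax(sum(net * axis) / nn, -1), 1))
    ang <= tol
  }, trackIds(tracks))
  trackSet(d[d$track_id %in% keepIds, , drop = FALSE],
           pixelSize = tracks@pixelSize, frameRate = tracks@frameRate)
}

#' Passive-movement flag
#'
#' Speeds below ~7 um/s are consistent with passive (non-swimming) motion.
#' The flag is a label only; it never filters data automatically.
#'
#' @param speed speed(s) in um/s.
#' @param threshold passive threshold, um/s.
#' @return Logical vector: TRUE = passive (strictly below threshold).
#' @examples
#' passiveFlag(c(2, 7, 27))  # TRUE FALSE FALSE
#' @export
passiveFlag <- function(speed, threshold = 7) {
  .checkNonNegative(speed, "speed")
  speed < threshold
}
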