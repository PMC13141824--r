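#' @import methods
NULL

#' Medium parameters
#'
#' Physical properties of the swimming medium. Only the dynamic viscosity
#' enters the Bean-model drag calculation; the default is the value used for
#' the hanging-drop assays (0.90e-3 Pa s, close to water at room temperature).
#'
#' @slot viscosity Dynamic viscosity in Pa s; must be > 0.
#' @export
setClass("MediumParams", representation(viscosity = "numeric"),
         prototype(viscosity = 0.90e-3),
         validity = function(object) {
           if (length(object@viscosity) != 1L || !is.finite(object@viscosity) ||
               object@viscosity <= 0)
             return("viscosity must be a single positive number (Pa s)")
           TRUE
         })

#' Construct medium parameters
#'
#' @param viscosity dynamic viscosity in Pa s (default 0.90e-3).
#' @return A \linkS4class{MediumParams} object.
#' @examples
#' mediumParams()
#' @export
mediumParams <- function(viscosity = 0.90e-3) {
  new("MediumParams", viscosity = viscosity)
}

#' Applied magnetic field protocol
#'
#' The magnetic flux density applied during an experiment: a static guiding
#' field (velocimetry) or a square wave whose direction reverses along a fixed
#' axis at listed times (U-turn magnetometry). The field direction at time t
#' is \code{axis * (-1)^k} where k is the number of reversal times <= t.
#'
#' @slot magnitude Flux density in tesla; >= 0.
#' @slot axis Unit 2-vector in the image plane.
#' @slot mode Either \code{"static"} or \code{"square_wave"}.
#' @slot reversalTimes Strictly increasing reversal times in seconds
#'   (empty for static protocols).
#' @export
setClass("FieldProtocol",
         representation(magnitude = "numeric", axis = "numeric",
                        mode = "character", reversalTimes = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(object@magnitude) != 1L || !is.finite(object@magnitude) ||
               object@magnitude < 0)
             msg <- c(msg, "magnitude must be a single number >= 0 (tesla)")
           if (length(object@axis) != 2L || !all(is.finite(object@axis)) ||
               abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
             msg <- c(msg, "axis must be a unit 2-vector")
           if (!object@mode %in% c("static", "square_wave"))
             msg <- c(msg, "mode must be 'static' or 'square_wave'")
           if (object@mode == "static" && length(object@reversalTimes) > 0L)
             msg <- c(msg, "static protocols carry no reversal times")
           if (length(object@reversalTimes) > 1L &&
               any(diff(object@reversalTimes) <= 0))
             msg <- c(msg, "reversalTimes must be strictly increasing")
           if (is.null(msg)) TRUE else msg
         })

#' Construct a field protocol
#'
#' @param magnitude flux density in tesla (default 2.55e-4 T, the pulsed-field
#'   strength used for U-turn magnetometry).
#' @param axis field axis as a 2-vector (normalised internally).
#' @param mode \code{"static"} or \code{"square_wave"}.
#' @param reversalTimes reversal times in seconds for square-wave protocols.
#' @return A \linkS4class{FieldProtocol}.
#' @examples
#' fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4, 6))
#' @export
fieldProtocol <- function(magnitude = 2.55e-4, axis = c(1, 0),
                          mode = c("static", "square_wave"),
                          reversalTimes = numeric(0)) {
  mode <- match.arg(mode)
  if (mode == "square_wave" && length(reversalTimes) == 0L)
    stop("square_wave protocols need at least one reversal time")
  n <- sqrt(sum(axis^2))
  .checkPositive(n, "axis norm")
  new("FieldProtocol", magnitude = magnitude, axis = axis / n, mode = mode,
      reversalTimes = as.numeric(reversalTimes))
}

#' Field direction at given times
#'
#' @param protocol a \linkS4class{FieldProtocol}.
#' @param t vector of times in seconds.
#' @return A length(t) x 2 matrix of unit direction vectors.
#' @export
fieldDirection <- function(protocol, t) {
  stopifnot(is(protocol, "FieldProtocol"))
  k <- vapply(t, function(ti) sum(protocol@reversalTimes <= ti), integer(1))
  sgn <- (-1)^k
  cbind(sgn * protocol@axis[1], sgn * protocol@axis[2])
}

#' Instantaneous state of a swimming cell
#'
#' @slot position 2-vector, micrometres.
#' @slot heading body-axis angle in radians, measured in the laboratory frame.
#' @slot speed swimming speed in micrometres per second; >= 0.
#' @slot moment magnetic moment in A m^2; >= 0.
#' @slot radius effective radius in micrometres; > 0.
#' @export
setClass("CellState",
         representation(position = "numeric", heading = "numeric",
                        speed = "numeric", moment = "numeric",
                        radius = "numeric"),
         validity = function(object) {
           msg <- NULL
           if (length(object@position) != 2L || !all(is.finite(object@position)))
             msg <- c(msg, "position must be a finite 2-vector (um)")
           if (length(object@speed) != 1L || object@speed < 0)
             msg <- c(msg, "speed must be >= 0 (um/s)")
           if (length(object@moment) != 1L || object@moment < 0)
             msg <- c(msg, "moment must be >= 0 (A m^2)")
           if (length(object@radius) != 1L || object@radius <= 0)
             msg <- c(msg, "radius must be > 0 (um)")
           if (is.null(msg)) TRUE else msg
         })

#' Construct a cell state
#'
#' @param position 2-vector, um.
#' @param heading laboratory-frame heading, rad.
#' @param speed swimming speed, um/s.
#' @param moment magnetic moment, A m^2.
#' @param radius effective radius, um.
#' @return A \linkS4class{CellState}.
#' @export
cellState <- function(position = c(0, 0), heading = 0, speed = 20,
                      moment = 1.5e-15, radius = 0.6) {
  new("CellState", position = as.numeric(position), heading = heading,
      speed = speed, moment = moment, radius = radius)
}

#' A set of reconstructed cell trajectories
#'
#' Wraps the interchange track table: one row per (track, frame) with time in
#' seconds and positions in micrometres. Frames are strictly increasing within
#' a track and (track_id, frame) pairs are unique.
#'
#' @slot data data.frame with columns track_id, frame, t_s, x_um, y_um,
#'   area_um2.
#' @slot pixelSize pixel scale in um/px (NA when tracks were born in um).
#' @slot frameRate acquisition frame rate in Hz (NA if unknown).
#' @export
setClass("TrackSet",
         representation(data = "data.frame", pixelSize = "numeric",
                        frameRate = "numeric"),
         validity = function(object) {
           need <- c("track_id", "frame", "t_s", "x_um", "y_um", "area_um2")
           miss <- setdiff(need, names(object@data))
           if (length(miss))
             return(paste("missing track columns:", paste(miss, collapse = ", ")))
           d <- object@data
           if (nrow(d)) {
             if (anyDuplicated(d[, c("track_id", "frame")]))
               return("duplicate (track_id, frame) rows")
             ## rows are stored sorted by (track, frame); frames strictly
             ## increase within each track in storage order
             bad <- tapply(d$frame, d$track_id, function(f) any(diff(f) <= 0))
             if (any(unlist(bad)))
               return("frames must be strictly increasing within a track")
           }
           TRUE
         })

#' Construct a TrackSet
#'
#' @param data data.frame with columns track_id, frame, t_s, x_um, y_um,
#'   area_um2; rows are sorted by (track_id, frame).
#' @param pixelSize pixel scale, um/px.
#' @param frameRate frame rate, Hz.
#' @return A \linkS4class{TrackSet}.
#' @export
trackSet <- function(data, pixelSize = NA_real_, frameRate = NA_real_) {
  data <- as.data.frame(data)
  if (nrow(data)) data <- data[order(data$track_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  new("TrackSet", data = data, pixelSize = pixelSize, frameRate = frameRate)
}

#' One fitted U-turn
#'
#' @slot width asymptotic U-turn width L in um.
#' @slot points canonical (x, y) coordinates in um, apex at the origin.
#' @slot residual RMS misfit normalised by L (dimensionless).
#' @slot nPoints number of points in the segment.
#' @slot converged logical; FALSE flags a rejected fit.
#' @slot speed mean speed over the segment, um/s.
#' @export
setClass("UTurnFit",
         representation(width = "numeric", points = "matrix",
                        residual = "numeric", nPoints = "integer",
                        converged = "logical", speed = "numeric"))

#' Per-track magnetic moment estimates
#'
#' @slot estimates data.frame: track_id, R_um, v_um_s, alpha, m_Am2, n_uturns.
#' @slot excluded data.frame: track_id, reason.
#' @slot field the \linkS4class{FieldProtocol} used.
#' @export
setClass("MomentEstimates",
         representation(estimates = "data.frame", excluded = "data.frame",
                        field = "FieldProtocol"))

#' A fitted multi-Gaussian population model
#'
#' Components are scaled bivariate Gaussians
#' a * exp(-q/2) with q the Mahalanobis form of covariance
#' [[s1^2, rho s1 s2], [rho s1 s2, s2^2]]; a is the peak amplitude so each
#' component integrates to a * 2 pi s1 s2 sqrt(1 - rho^2).
#'
#' @slot components data.frame with columns mu1, mu2, sigma1, sigma2, rho, a.
#' @slot aic AIC of the selected model.
#' @slot aicTable data.frame of the sweep: n, rss, aic.
#' @slot shares per-component PDF-volume shares (sum to 1).
#' @slot significant logical flags (share >= minShare).
#' @slot minShare the significance threshold used.
#' @slot objective "surface" (least squares against a KDE surface) or "mle".
#' @export
setClass("PopulationModel",
         representation(components = "data.frame", aic = "numeric",
                        aicTable = "data.frame", shares = "numeric",
                        significant = "logical", minShare = "numeric",
                        objective = "character"),
         validity = function(object) {
           need <- c("mu1", "mu2", "sigma1", "sigma2", "rho", "a")
           miss <- setdiff(need, names(object@components))
           if (length(miss))
             return(paste("missing component columns:",
                          paste(miss, collapse = ", ")))
           cc <- object@components
           if (nrow(cc) && (any(cc$sigma1 <= 0) || any(cc$sigma2 <= 0) ||
                            any(abs(cc$rho) >= 1) || any(cc$a < 0)))
             return("components must have sigma > 0, |rho| < 1, a >= 0")
           TRUE
         })

#' Error-weighted critical-radius fit
#'
#' Linear model m = b0 + b1 R with weights 1/sigma_m^2; the critical radius
#' r_c = -b0/b1 is the radius below which the fitted moment is zero.
#'
#' @slot slope b1 and its standard error.
#' @slot intercept b0 and its standard error.
#' @slot rc critical radius in um (NA when b1 <= 0).
#' @slot rcSE delta-method standard error of r_c.
#' @slot fit the underlying \code{lm} object.
#' @export
setClass("CriticalRadiusFit",
         representation(slope = "numeric", intercept = "numeric",
                        rc = "numeric", rcSE = "numeric", fit = "ANY"))

#' Directional quantile envelope
#'
#' Convex region obtained by intersecting, over many directions u, the
#' half-planes \{x : <x - centre, u> <= q-quantile of projections\}.
#'
#' @slot q quantile level.
#' @slot nDirections number of projection directions.
#' @slot vertices closed polygon vertices (last row repeats the first).
#' @slot centre the data centre used for projections.
#' @export
setClass("QuantileEnvelope",
         representation(q = "numeric", nDirections = "integer",
                        vertices = "matrix", centre = "numeric"))
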