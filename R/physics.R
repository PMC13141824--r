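## Bean-model physics: a magnetotactic cell is a self-propelled magnetic
## dipole swimming at constant speed v along its body axis, whose orientation
## relaxes towards the applied field under the torque balance
##   alpha dphi/dt = -m B sin(phi),
## phi the angle between body axis and field. A field reversal sends the cell
## through a U-turn whose asymptotic width L = pi v alpha / (m B) encodes m.

#' Rotational drag coefficient
#'
#' Sphere-equivalent rotational drag of a cell of effective radius R in a
#' medium of viscosity eta. The default convention is alpha = 8 pi^2 eta R^3;
#' the classic Stokes sphere value 8 pi eta R^3 (a factor pi smaller) is
#' available via \code{convention = "sphere"}.
#'
#' @param R effective radius in micrometres.
#' @param eta dynamic viscosity in Pa s (default 0.90e-3).
#' @param convention \code{"pisq"} for 8 pi^2 eta R^3 (default) or
#'   \code{"sphere"} for 8 pi eta R^3.
#' @return Drag coefficient in SI units (kg m^2 / s).
#' @examples
#' rotationalDrag(1)                      # ~7.106e-20
#' rotationalDrag(1, convention = "sphere")
#' @export
rotationalDrag <- function(R, eta = 0.90e-3, convention = c("pisq", "sphere")) {
  convention <- match.arg(convention)
  .checkPositive(R, "R")
  .checkPositive(eta, "eta")
  pref <- if (convention == "pisq") 8 * pi^2 else 8 * pi
  pref * eta * .asMetres(R)^3
}

#' Effective radius from detected area
#'
#' Radius of the circle with the same area as the detected 2D cell footprint.
#'
#' @param area cell area in square micrometres.
#' @return Effective radius in micrometres.
#' @examples
#' effectiveRadius(pi)  # 1
#' @export
effectiveRadius <- function(area) {
  .checkPositive(area, "area")
  sqrt(area / pi)
}

#' Theoretical U-turn shape
#'
#' The canonical U-turn path y(x) = -(L/pi) ln(sec(pi x / L)): even in x,
#' zero at the apex x = 0, and diverging to -Inf as |x| -> L/2 (the two
#' straight legs of the turn, separated by the asymptotic width L).
#'
#' @param x transverse coordinate(s) in um; requires |x| < L/2.
#' @param L asymptotic U-turn width in um.
#' @return y coordinate(s) in um.
#' @examples
#' uturnShape(0, 10)        # 0
#' uturnShape(2.5, 10)      # -(10/pi) * log(sqrt(2))
#' @export
uturnShape <- function(x, L) {
  .checkPositive(L, "L")
  if (any(abs(x) >= L / 2))
    stop("uturnShape is defined for |x| < L/2", call. = FALSE)
  -(L / pi) * log(1 / cos(pi * x / L))
}

#' Magnetic moment from a fitted U-turn
#'
#' Inverts the Bean-model width relation L = pi v alpha / (m B):
#' m = pi alpha v / (B L), with alpha = \code{\link{rotationalDrag}}(R, eta).
#' Arguments are in the package's external units and converted to SI
#' internally.
#'
#' @param L asymptotic U-turn width, um.
#' @param v swimming speed over the U-turn, um/s.
#' @param R effective radius, um.
#' @param B flux density of the pulsed field, tesla (default 2.55e-4).
#' @param eta medium viscosity, Pa s.
#' @param convention drag convention, see \code{\link{rotationalDrag}}.
#' @return Magnetic moment in A m^2.
#' @examples
#' momentFromUturn(L = 30, v = 30, R = 1)  # ~8.75e-16 A m^2
#' @export
momentFromUturn <- function(L, v, R, B = 2.55e-4, eta = 0.90e-3,
                            convention = c("pisq", "sphere")) {
  .checkPositive(L, "L")
  .checkPositive(v, "v")
  .checkPositive(B, "B")
  alpha <- rotationalDrag(R, eta, convention)
  pi * alpha * .asMetres(v) / (B * .asMetres(L))
}

#' Closed-form heading relaxation
#'
#' Analytic solution of alpha dphi/dt = -m B sin(phi):
#' tan(phi(t)/2) = tan(phi0/2) exp(-t / tau) with tau = alpha / (m B).
#' Used as an independent oracle for the numerical integrator.
#'
#' @param t time(s) in seconds.
#' @param phi0 initial angle to the field, rad (0 < phi0 < pi).
#' @param tau relaxation time alpha/(m B), seconds.
#' @return phi(t) in radians.
#' @export
headingClosedForm <- function(t, phi0, tau) {
  .checkPositive(tau, "tau")
  2 * atan(tan(phi0 / 2) * exp(-t / tau))
}

#' Bean-model relaxation time
#'
#' @param cell a \linkS4class{CellState} (or a moment in A m^2 when
#'   \code{R} is given).
#' @param B flux density, tesla.
#' @param medium a \linkS4class{MediumParams}.
#' @param convention drag convention.
#' @return tau = alpha / (m B) in seconds.
#' @export
relaxationTime <- function(cell, B, medium = mediumParams(),
                           convention = c("pisq", "sphere")) {
  stopifnot(is(cell, "CellState"))
  .checkPositive(cell@moment, "moment")
  rotationalDrag(cell@radius, medium@viscosity, convention) /
    (cell@moment * B)
}

#' Simulate a Bean-model trajectory
#'
#' Integrates the heading equation alpha dphi/dt = -m B sin(phi) (fixed-step
#' RK4, optional white rotational noise) together with dx/dt =
#' v (cos theta, sin theta) in the laboratory frame, where phi is the angle
#' between the heading theta and the current field direction. At each reversal
#' the field direction flips; exact anti-alignment is an unstable equilibrium,
#' so a residual misalignment of at least \code{epsilon} radians is enforced
#' after each flip.
#'
#' @param cell initial \linkS4class{CellState}.
#' @param field a \linkS4class{FieldProtocol}.
#' @param medium a \linkS4class{MediumParams}.
#' @param dt integration/sampling step, s.
#' @param duration total simulated time, s.
#' @param rotationalNoise rotational diffusivity D_r in rad^2/s (0 = none).
#' @param epsilon minimum post-reversal misalignment, rad.
#' @param seed RNG seed for the noise (ignored when noise is 0).
#' @param convention drag convention, see \code{\link{rotationalDrag}}.
#' @param trackId id assigned to the output track.
#' @return A \linkS4class{TrackSet} with one track sampled at dt; the
#'   per-frame area is the constant pi R^2.
#' @examples
#' fp <- fieldProtocol(mode = "square_wave", reversalTimes = 2)
#' ts <- simulateTrajectory(cellState(), fp, dt = 0.01, duration = 4)
#' @export
simulateTrajectory <- function(cell, field, medium = mediumParams(),
                               dt = 0.01, duration = 2, rotationalNoise = 0,
                               epsilon = 1e-3, seed = NULL,
                               convention = c("pisq", "sphere"),
                               trackId = 1L) {
  stopifnot(is(cell, "CellState"), is(field, "FieldProtocol"))
  .checkPositive(dt, "dt")
  .stopIfNot(duration >= dt, "duration must be >= dt")
  convention <- match.arg(convention)

  n <- floor(duration / dt)
  times <- (0:n) * dt
  theta <- numeric(n + 1L)
  xy <- matrix(0, n + 1L, 2L)
  theta[1] <- cell@heading
  xy[1, ] <- cell@position

  B <- field@magnitude
  torque <- cell@moment > 0 && B > 0
  invTau <- if (torque)
    1 / relaxationTime(cell, B, medium, convention) else 0

  psi0 <- atan2(field@axis[2], field@axis[1])
  rev <- field@reversalTimes
  psiAt <- function(t) psi0 + pi * (sum(rev <= t) %% 2)

  noisy <- rotationalNoise > 0
  noise <- if (noisy) .withSeed(seed, stats::rnorm(n)) *
    sqrt(2 * rotationalNoise * dt) else NULL

  dtheta <- function(th, psi) -invTau * sin(th - psi)
  psiPrev <- psiAt(0)
  for (i in seq_len(n)) {
    t0 <- times[i]
    psi <- psiAt(t0)
    if (psi != psiPrev && torque) {
      ## post-flip nudge away from the unstable anti-aligned equilibrium
      d <- .wrapAngle(theta[i] - psi)
      if (abs(d) > pi - epsilon)
        theta[i] <- psi + sign(d) * (pi - epsilon)
      psiPrev <- psi
    }
    th <- theta[i]
    k1 <- dtheta(th, psi)
    k2 <- dtheta(th + dt / 2 * k1, psi)
    k3 <- dtheta(th + dt / 2 * k2, psi)
    k4 <- dtheta(th + dt * k3, psi)
    thNew <- th + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (noisy) thNew <- thNew + noise[i]
    ## displacement along the mid-step heading keeps |dx/dt| = v exactly
    mid <- (th + thNew) / 2
    xy[i + 1L, ] <- xy[i, ] + cell@speed * dt * c(cos(mid), sin(mid))
    theta[i + 1L] <- thNew
  }

  d <- data.frame(track_id = trackId, frame = 0:n, t_s = times,
                  x_um = xy[, 1], y_um = xy[, 2],
                  area_um2 = pi * cell@radius^2)
  attr(d, "heading") <- theta
  ts <- trackSet(d, frameRate = 1 / dt)
  attr(ts, "heading") <- theta
  ts
}
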