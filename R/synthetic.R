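## Synthetic ground-truth generators: population samples in (log10 v, R)
## space, Bean-model U-turn track sets, and rendered grayscale image stacks.
## These stand in for archived raw microscopy data in every test.

#' Population specification
#'
#' A mixture of bivariate Gaussian components in (log10 speed, radius) space,
#' plus a rule assigning each cell a magnetic moment: either per-component
#' Gaussian moments or the linear size law m = slope * (R - rc) clipped at 0
#' (cells below the critical radius rc are non-magnetic).
#'
#' @param components data.frame with columns mu1 (mean log10 speed, um/s),
#'   mu2 (mean radius, um), sigma1, sigma2, rho and optionally weight.
#'   Missing weights default to equal.
#' @param momentModel either \code{list(type = "linear", slope, rc)} with
#'   slope in A m^2 per um and rc in um, or
#'   \code{list(type = "gaussian", mean, sd)} with per-component vectors in
#'   A m^2.
#' @return A list of class \code{"PopulationSpec"}.
#' @examples
#' populationSpec(data.frame(mu1 = 1.4, mu2 = 0.69, sigma1 = 0.17,
#'                           sigma2 = 0.13, rho = -0.05))
#' @export
populationSpec <- function(components,
                           momentModel = list(type = "linear",
                                              slope = 5e-15, rc = 0.57)) {
  components <- as.data.frame(components)
  need <- c("mu1", "mu2", "sigma1", "sigma2", "rho")
  miss <- setdiff(need, names(components))
  if (length(miss))
    stop("missing component columns: ", paste(miss, collapse = ", "))
  if (is.null(components$weight))
    components$weight <- 1 / nrow(components)
  .checkNonNegative(components$weight, "weight")
  .stopIfNot(sum(components$weight) > 0, "weights must sum to > 0")
  components$weight <- components$weight / sum(components$weight)
  .checkPositive(components$sigma1, "sigma1")
  .checkPositive(components$sigma2, "sigma2")
  .stopIfNot(all(abs(components$rho) < 1), "|rho| must be < 1")
  structure(list(components = components, momentModel = momentModel),
            class = "PopulationSpec")
}

## Draw n points from a single bivariate Gaussian via its Cholesky factor.
.rmvn2 <- function(n, mu1, mu2, s1, s2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x <- mu1 + s1 * z1
  y <- mu2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  cbind(x, y)
}

#' Sample points from a Gaussian mixture
#'
#' Generic component-wise sampler used by \code{\link{samplePopulation}} and
#' by the population-analysis tests; axes are whatever the component table
#' means (e.g. (log10 v, R) or (m, R)).
#'
#' @param components data.frame with mu1, mu2, sigma1, sigma2, rho and
#'   optionally weight (equal when absent).
#' @param n total number of draws.
#' @param seed RNG seed.
#' @return n x 2 matrix with a \code{"component"} attribute of generating
#'   component indices.
#' @export
sampleMixture <- function(components, n, seed = NULL) {
  components <- as.data.frame(components)
  if (is.null(components$weight))
    components$weight <- 1 / nrow(components)
  w <- components$weight / sum(components$weight)
  .withSeed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE, prob = w)
    out <- matrix(NA_real_, n, 2L)
    for (k in seq_len(nrow(components))) {
      idx <- which(comp == k)
      if (!length(idx)) next
      cc <- components[k, ]
      out[idx, ] <- .rmvn2(length(idx), cc$mu1, cc$mu2, cc$sigma1, cc$sigma2,
                           cc$rho)
    }
    attr(out, "component") <- comp
    out
  })
}

#' Sample a cell population
#'
#' Draws cells component-wise from the bivariate Gaussians of a
#' \code{\link{populationSpec}} in (log10 v, R) space, converts speeds back
#' to um/s, and assigns moments per the spec's moment model. Radii are
#' truncated below at 0.05 um (a Gaussian tail guard; the generating
#' components place negligible mass there).
#'
#' @param spec a \code{PopulationSpec}.
#' @param n number of cells.
#' @param seed RNG seed; identical seeds give identical samples.
#' @return data.frame: cell_id, component, v_um_s, R_um, m_Am2, log10_v.
#' @export
samplePopulation <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "PopulationSpec"))
  pts <- sampleMixture(spec$components, n, seed)
  comp <- attr(pts, "component")
  v <- 10^pts[, 1]
  R <- pmax(pts[, 2], 0.05)
  mm <- spec$momentModel
  m <- .withSeed(if (is.null(seed)) NULL else seed + 1L, {
    if (identical(mm$type, "linear")) {
      pmax(mm$slope * (R - mm$rc), 0)
    } else if (identical(mm$type, "gaussian")) {
      pmax(stats::rnorm(n, mm$mean[comp], mm$sd[comp]), 0)
    } else stop("unknown moment model type: ", mm$type)
  })
  data.frame(cell_id = seq_len(n), component = comp, v_um_s = v, R_um = R,
             m_Am2 = m, log10_v = pts[, 1])
}

#' Generate a ground-truth U-turn dataset
#'
#' Simulates one Bean-model track per cell under a square-wave field spanning
#' all reversals, and emits the ground truth alongside, including the
#' theoretical asymptotic width L = pi v alpha / (m B).
#'
#' @param spec a \code{PopulationSpec}.
#' @param field a square-wave \linkS4class{FieldProtocol}.
#' @param nCells number of cells.
#' @param dt sampling step, s.
#' @param medium a \linkS4class{MediumParams}.
#' @param rotationalNoise rotational diffusivity, rad^2/s.
#' @param positionNoise Gaussian centroid noise added to positions, um.
#' @param duration total simulated time (default: past the last reversal by
#'   one inter-reversal period).
#' @param seed RNG seed.
#' @param fov field-of-view width for random starting positions, um.
#' @param convention drag convention, see \code{\link{rotationalDrag}}.
#' @return list(tracks = \linkS4class{TrackSet}, truth = data.frame with
#'   cell_id, v_um_s, R_um, m_Am2, L_theory_um).
#' @export
genUturnDataset <- function(spec, field, nCells, dt = 0.02,
                            medium = mediumParams(), rotationalNoise = 0,
                            positionNoise = 0, duration = NULL, seed = 1,
                            fov = 400, convention = c("pisq", "sphere")) {
  stopifnot(is(field, "FieldProtocol"))
  if (field@mode != "square_wave")
    stop("genUturnDataset requires a square-wave field protocol")
  convention <- match.arg(convention)
  cells <- samplePopulation(spec, nCells, seed)
  rev <- field@reversalTimes
  if (is.null(duration))
    duration <- max(rev) + if (length(rev) > 1) stats::median(diff(rev)) else max(rev)

  alpha <- rotationalDrag(cells$R_um, medium@viscosity, convention)
  Lth <- ifelse(cells$m_Am2 > 0,
                pi * cells$v_um_s * alpha / (cells$m_Am2 * field@magnitude),
                NA_real_)

  sub <- .childSeeds(seed, nCells)
  dts <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    pos <- .withSeed(sub[i], stats::runif(2, -fov / 2, fov / 2))
    cs <- cellState(position = pos, heading = 0, speed = cells$v_um_s[i],
                    moment = cells$m_Am2[i], radius = cells$R_um[i])
    tr <- simulateTrajectory(cs, field, medium, dt = dt, duration = duration,
                             rotationalNoise = rotationalNoise,
                             seed = sub[i] + 1L, convention = convention,
                             trackId = i)
    d <- trackData(tr)
    if (positionNoise > 0) {
      eps <- .withSeed(sub[i] + 2L,
                       matrix(stats::rnorm(2L * nrow(d), 0, positionNoise),
                              ncol = 2L))
      d$x_um <- d$x_um + eps[, 1]
      d$y_um <- d$y_um + eps[, 2]
    }
    dts[[i]] <- d
  }
  tracks <- trackSet(do.call(rbind, dts), frameRate = 1 / dt)
  truth <- data.frame(cell_id = cells$cell_id, v_um_s = cells$v_um_s,
                      R_um = cells$R_um, m_Am2 = cells$m_Am2,
                      L_theory_um = Lth)
  list(tracks = tracks, truth = truth)
}

#' Rendering specification for synthetic image stacks
#'
#' @param width,height image size in pixels.
#' @param pixelSize pixel scale in um/px.
#' @param frameRate frame rate in Hz.
#' @param spotSigmaFactor Gaussian spot sigma as a fraction of R/pixelSize
#'   (an arbitrary appearance stand-in; cell optics are not modelled).
#' @param peakIntensity spot peak amplitude for a 1 um^2 cell, in [0, 1]
#'   image units; total flux scales with cell area.
#' @param background constant background offset in [0, 1].
#' @param gradientAmplitude peak-to-peak amplitude of a linear illumination
#'   gradient across the frame.
#' @param gaussianNoise read-noise standard deviation in image units.
#' @param poissonNoise logical; apply Poisson shot noise (at
#'   \code{photonsPerUnit} photons per unit intensity).
#' @param photonsPerUnit photon count corresponding to intensity 1.0.
#' @param stuckFraction fraction of extra motionless nuisance cells added.
#' @param bits TIFF bit depth used when the stack is written (8 or 16).
#' @return list of class \code{"RenderSpec"}.
#' @export
renderSpec <- function(width = 256, height = 256, pixelSize = 0.25,
                       frameRate = 50, spotSigmaFactor = 0.8,
                       peakIntensity = 2, background = 0.1,
                       gradientAmplitude = 0, gaussianNoise = 0,
                       poissonNoise = FALSE, photonsPerUnit = 2000,
                       stuckFraction = 0, bits = 16) {
  .checkPositive(pixelSize, "pixelSize")
  .checkPositive(frameRate, "frameRate")
  structure(as.list(environment()), class = "RenderSpec")
}

#' Render tracks into a synthetic microscopy stack
#'
#' Each cell is drawn as an isotropic Gaussian intensity spot whose total
#' flux is proportional to its area, over a constant background plus an
#' optional linear illumination gradient; Poisson and/or Gaussian noise is
#' added per the spec. Positions are mapped um -> px by the pixel scale
#' (0-based pixel coordinates, origin at the top-left pixel centre).
#'
#' @param tracks a \linkS4class{TrackSet} (positions in um; at least one
#'   point of some track must fall inside the field of view).
#' @param spec a \code{\link{renderSpec}}.
#' @param seed RNG seed for noise and nuisance cells.
#' @return list(stack = numeric array width x height x frames in [0, 1],
#'   truth = data.frame(frame, cell_id, x_px, y_px, area_px2)).
#' @export
renderStack <- function(tracks, spec, seed = 1) {
  stopifnot(is(tracks, "TrackSet"), inherits(spec, "RenderSpec"))
  d <- trackData(tracks)
  if (!nrow(d)) stop("empty track list: nothing to render")
  frames <- sort(unique(d$frame))
  nf <- length(frames)
  W <- spec$width; H <- spec$height; sc <- spec$pixelSize

  xpx <- d$x_um / sc
  ypx <- d$y_um / sc
  inside <- xpx >= 0 & xpx <= W - 1 & ypx >= 0 & ypx <= H - 1
  if (!any(inside)) stop("no track point falls inside the field of view")

  ## static nuisance cells
  nStuck <- round(spec$stuckFraction * nTracks(tracks))
  stuck <- if (nStuck > 0) .withSeed(seed + 7L, {
    data.frame(x = stats::runif(nStuck, 0, W - 1),
               y = stats::runif(nStuck, 0, H - 1),
               R = stats::runif(nStuck, 0.3, 0.9))
  }) else NULL

  grad <- if (spec$gradientAmplitude > 0) {
    gx <- matrix(seq(0, 1, length.out = W), W, H)
    spec$gradientAmplitude * gx
  } else 0

  drawSpot <- function(img, cx, cy, R_um) {
    sig <- pmax(spec$spotSigmaFactor * R_um / sc, 0.6)
    amp <- spec$peakIntensity * (pi * R_um^2)  # flux ~ area
    ## normalise so that peak height stays moderate while flux tracks area
    amp <- amp / (2 * pi * sig^2) * 4
    r <- ceiling(4 * sig)
    ix <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
    iy <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
    if (!length(ix) || !length(iy)) return(img)
    g <- outer(exp(-(ix - cx)^2 / (2 * sig^2)),
               exp(-(iy - cy)^2 / (2 * sig^2)))
    img[ix + 1L, iy + 1L] <- img[ix + 1L, iy + 1L] + amp * g
    img
  }

  stack <- array(0, dim = c(W, H, nf))
  truth <- vector("list", nf)
  noiseSeeds <- .childSeeds(seed, nf)
  for (j in seq_len(nf)) {
    f <- frames[j]
    img <- matrix(spec$background, W, H) + grad
    sel <- which(d$frame == f & inside)
    for (i in sel) {
      R_um <- sqrt(d$area_um2[i] / pi)
      img <- drawSpot(img, xpx[i], ypx[i], R_um)
    }
    if (!is.null(stuck))
      for (k in seq_len(nrow(stuck)))
        img <- drawSpot(img, stuck$x[k], stuck$y[k], stuck$R[k])
    img <- .withSeed(noiseSeeds[j], {
      if (spec$poissonNoise)
        img <- stats::rpois(length(img), img * spec$photonsPerUnit) /
          spec$photonsPerUnit
      if (spec$gaussianNoise > 0)
        img <- img + stats::rnorm(length(img), 0, spec$gaussianNoise)
      matrix(img, W, H)
    })
    stack[, , j] <- pmin(pmax(img, 0), 1)
    truth[[j]] <- if (length(sel))
      data.frame(frame = f, cell_id = d$track_id[sel], x_px = xpx[sel],
                 y_px = ypx[sel], area_px2 = d$area_um2[sel] / sc^2)
    else NULL
  }
  list(stack = stack, truth = do.call(rbind, truth))
}
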