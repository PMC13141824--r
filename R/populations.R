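## Population identification: 2D kernel density surfaces (Sheather-Jones
## bandwidth, Epanechnikov product kernel), AIC-constrained multi-Gaussian
## decomposition fitted to the surface by differential evolution,
## PDF-volume significance selection, the error-weighted critical-radius
## fit, and directional quantile envelopes.

#' 2D kernel density estimate
#'
#' Binned product-kernel KDE with a per-axis Sheather-Jones bandwidth and an
#' Epanechnikov kernel (scaled so its standard deviation equals the
#' bandwidth, matching \code{stats::density} conventions). The grid
#' integrates to 1.
#'
#' @param points n x 2 matrix (n >= 10).
#' @param bandwidth \code{"sj"} or a numeric 2-vector of bandwidths.
#' @param gridSize number of grid cells per axis.
#' @param kernel \code{"epanechnikov"} or \code{"gaussian"}.
#' @return list(x, y, z, bandwidth): axis midpoints and the density matrix
#'   (length(x) rows).
#' @examples
#' pts <- cbind(rnorm(500), rnorm(500))
#' d <- kde2d(pts)
#' sum(d$z) * diff(d$x[1:2]) * diff(d$y[1:2])  # ~1
#' @export
kde2d <- function(points, bandwidth = "sj", gridSize = 96,
                  kernel = c("epanechnikov", "gaussian")) {
  kernel <- match.arg(kernel)
  points <- as.matrix(points)
  .stopIfNot(ncol(points) == 2L && nrow(points) >= 10L,
             "points must be an n x 2 matrix with n >= 10")
  if (any(apply(points, 2, stats::sd) == 0))
    stop("degenerate (constant) axis", call. = FALSE)
  bw <- if (identical(bandwidth, "sj"))
    c(stats::bw.SJ(points[, 1]), stats::bw.SJ(points[, 2]))
  else { .checkPositive(bandwidth, "bandwidth"); rep(bandwidth, length.out = 2) }

  ## support half-widths: Epanechnikov with sd h spans h*sqrt(5)
  half <- if (kernel == "epanechnikov") bw * sqrt(5) else bw * 4
  lo <- apply(points, 2, min) - half
  hi <- apply(points, 2, max) + half
  nx <- gridSize; ny <- gridSize
  dx <- (hi[1] - lo[1]) / nx
  dy <- (hi[2] - lo[2]) / ny
  xm <- lo[1] + (seq_len(nx) - 0.5) * dx
  ym <- lo[2] + (seq_len(ny) - 0.5) * dy

  ## bin counts then convolve with the separable kernel
  ix <- pmin(pmax(ceiling((points[, 1] - lo[1]) / dx), 1L), nx)
  iy <- pmin(pmax(ceiling((points[, 2] - lo[2]) / dy), 1L), ny)
  cnt <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
  cnt[] <- as.numeric(tab)

  k1d <- function(h, step) {
    r <- ceiling(if (kernel == "epanechnikov") h * sqrt(5) / step else 4 * h / step)
    u <- (-r:r) * step
    w <- if (kernel == "epanechnikov") {
      a <- h * sqrt(5)
      pmax(1 - (u / a)^2, 0)
    } else exp(-u^2 / (2 * h^2))
    w / sum(w)
  }
  convAxis <- function(mat, w, along) {
    r <- (length(w) - 1L) / 2L
    out <- matrix(0, nrow(mat), ncol(mat))
    for (s in -r:r) {
      wt <- w[s + r + 1L]
      if (wt == 0) next
      if (along == 1L) {
        i1 <- max(1L, 1L - s):min(nrow(mat), nrow(mat) - s)
        out[i1 + s, ] <- out[i1 + s, ] + wt * mat[i1, ]
      } else {
        j1 <- max(1L, 1L - s):min(ncol(mat), ncol(mat) - s)
        out[, j1 + s] <- out[, j1 + s] + wt * mat[, j1]
      }
    }
    out
  }
  z <- convAxis(cnt, k1d(bw[1], dx), 1L)
  z <- convAxis(z, k1d(bw[2], dy), 2L)
  z <- z / (sum(z) * dx * dy)
  list(x = xm, y = ym, z = z, bandwidth = bw)
}

#' Differential evolution optimizer
#'
#' Differential evolution with bounce-back bound handling; deterministic
#' under a fixed seed. Mutation is best/1/bin with dither by default
#' (fast convergence on smooth landscapes); \code{strategy = "rand"} gives
#' the classic rand/1/bin.
#'
#' @param fn objective function of a parameter vector.
#' @param lower,upper bound vectors.
#' @param popSize population size (default 15 x dimension).
#' @param maxIter number of generations.
#' @param F mutation weight (dithered uniformly in [0.5, F + 0.3] for the
#'   best/1 strategy).
#' @param CR crossover rate.
#' @param strategy \code{"best"} or \code{"rand"}.
#' @param seed RNG seed.
#' @param tol early stop when the population spread of objective values
#'   falls below tol (0 disables).
#' @param init optional matrix of initial members (rows; clipped to the
#'   bounds) replacing the first rows of the random population.
#' @return list(par, value, iterations).
#' @export
diffEvolution <- function(fn, lower, upper, popSize = NULL, maxIter = 200,
                          F = 0.8, CR = 0.9, strategy = c("best", "rand"),
                          seed = NULL, tol = 1e-10, init = NULL) {
  strategy <- match.arg(strategy)
  d <- length(lower)
  .stopIfNot(length(upper) == d && all(upper > lower), "bad bounds")
  if (is.null(popSize)) popSize <- 15L * d
  popSize <- max(popSize, 6L)
  .withSeed(seed, {
    pop <- matrix(stats::runif(popSize * d, lower, upper), popSize, d,
                  byrow = TRUE)
    if (!is.null(init)) {
      init <- matrix(pmin(pmax(t(init), lower), upper), ncol = d,
                     byrow = TRUE)
      k <- min(nrow(init), popSize)
      pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
    }
    val <- apply(pop, 1, fn)
    iter <- 0L
    for (iter in seq_len(maxIter)) {
      bestPar <- pop[which.min(val), ]
      for (i in seq_len(popSize)) {
        idx <- sample.int(popSize, 3L)
        while (any(idx == i)) idx <- sample.int(popSize, 3L)
        mut <- if (strategy == "best") {
          Fd <- stats::runif(1, 0.5, F + 0.3)
          bestPar + Fd * (pop[idx[2], ] - pop[idx[3], ])
        } else {
          pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        }
        ## bounce back into the box
        below <- mut < lower; above <- mut > upper
        mut[below] <- lower[below] + stats::runif(sum(below)) *
          (pop[i, below] - lower[below])
        mut[above] <- upper[above] - stats::runif(sum(above)) *
          (upper[above] - pop[i, above])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        fv <- fn(trial)
        if (fv <= val[i]) { pop[i, ] <- trial; val[i] <- fv }
      }
      if (tol > 0 && diff(range(val)) < tol) break
    }
    b <- which.min(val)
    list(par = pop[b, ], value = val[b], iterations = iter)
  })
}

## Basis matrix of unit-peak bivariate Gaussians on a grid.
## theta5: per component (mu1, mu2, s1, s2, rho); one column per component.
.mixBasis <- function(theta5, gx, gy) {
  n <- length(theta5) / 5L
  A <- matrix(0, length(gx) * length(gy), n)
  for (k in seq_len(n)) {
    p <- theta5[(5 * (k - 1) + 1):(5 * k)]
    om <- 1 - p[5]^2
    u <- (gx - p[1]) / p[3]
    v <- (gy - p[2]) / p[4]
    q <- outer(u^2, v^2, "+") - 2 * p[5] * outer(u, v)
    A[, k] <- exp(-q / (2 * om))
  }
  A
}

## Optimal non-negative amplitudes for a basis A against surface z
## (variable projection: amplitudes are linear, so they are solved exactly).
.nnlsAmplitudes <- function(A, z) {
  a <- tryCatch(solve(crossprod(A), crossprod(A, z)),
                error = function(e) NULL)
  if (is.null(a) || any(a < 0)) {
    a <- tryCatch(pracma::lsqnonneg(A, z)$x, error = function(e) NULL)
    if (is.null(a)) return(NULL)
  }
  as.numeric(a)
}

## Evaluate a sum of scaled bivariate Gaussians on a grid.
## theta: per component (mu1, mu2, s1, s2, rho, a); amplitude a is the peak.
.mixSurface <- function(theta, gx, gy) {
  n <- length(theta) / 6L
  z <- matrix(0, length(gx), length(gy))
  for (k in seq_len(n)) {
    p <- theta[(6 * (k - 1) + 1):(6 * k)]
    mu1 <- p[1]; mu2 <- p[2]; s1 <- p[3]; s2 <- p[4]; rho <- p[5]; a <- p[6]
    om <- 1 - rho^2
    u <- (gx - mu1) / s1
    v <- (gy - mu2) / s2
    ## outer quadratic form: u^2 - 2 rho u v + v^2, scaled by 1/om
    q <- outer(u^2, v^2, "+") - 2 * rho * outer(u, v)
    z <- z + a * exp(-q / (2 * om))
  }
  z
}

#' Fit an AIC-constrained multi-Gaussian population model
#'
#' For each candidate component count n, fits a sum of scaled bivariate
#' Gaussians G(mu1, mu2, sigma1, sigma2, rho, a) to the KDE surface of the
#' data by differential evolution (least squares over the grid), followed by
#' a local L-BFGS-B polish; the model minimising
#' AIC = N ln(RSS/N) + 2k (N grid cells, k = 6n parameters) is returned,
#' preferring the smallest n within \code{deltaAIC} of the minimum. An
#' alternative maximum-likelihood objective fits the mixture to the raw
#' points with weights proportional to the component volumes.
#'
#' @param points n x 2 data matrix (axes e.g. (log10 v, R) or (m, R)).
#' @param nRange candidate component counts.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param gridSize KDE grid size per axis.
#' @param bandwidth KDE bandwidth spec (see \code{\link{kde2d}}).
#' @param popFactor DE population size per parameter.
#' @param maxIter DE generations per candidate n.
#' @param deltaAIC tie-break band: smallest n within this of the minimum
#'   AIC wins.
#' @param minShare significance threshold forwarded to
#'   \code{\link{significanceFilter}}.
#' @param objective \code{"surface"} (default) or \code{"mle"}.
#' @param surface optionally a precomputed \code{\link{kde2d}} result.
#' @return A \linkS4class{PopulationModel} (already significance-flagged).
#' @export
fitMixtureSweep <- function(points, nRange = 1:4, seed = 1, gridSize = 64,
                            bandwidth = "sj", popFactor = 15, maxIter = 250,
                            deltaAIC = 2, minShare = 0.05,
                            objective = c("surface", "mle"),
                            surface = NULL) {
  objective <- match.arg(objective)
  points <- as.matrix(points)
  if (is.null(surface))
    surface <- kde2d(points, bandwidth = bandwidth, gridSize = gridSize)
  gx <- surface$x; gy <- surface$y; z <- surface$z
  N <- length(z)

  rg1 <- range(points[, 1]); rg2 <- range(points[, 2])
  ex1 <- diff(rg1) * 0.2; ex2 <- diff(rg2) * 0.2
  zmax <- max(z)

  zv <- as.vector(z)
  fits <- list()
  aicRows <- list()
  prevPar <- NULL
  nRange <- sort(nRange)
  npar <- if (objective == "surface") 5L else 6L
  for (n in nRange) {
    lo1 <- c(rg1[1] - ex1, rg2[1] - ex2, diff(rg1) / 100,
             diff(rg2) / 100, -0.95)
    up1 <- c(rg1[2] + ex1, rg2[2] + ex2, diff(rg1), diff(rg2), 0.95)
    if (objective == "mle") { lo1 <- c(lo1, 0); up1 <- c(up1, 1.5 * zmax) }
    lower <- rep(lo1, n)
    upper <- rep(up1, n)
    obj <- if (objective == "surface") {
      ## variable projection: shapes via DE, amplitudes solved exactly
      function(th) {
        A <- .mixBasis(th, gx, gy)
        a <- .nnlsAmplitudes(A, zv)
        if (is.null(a)) return(1e10)
        sum((A %*% a - zv)^2)
      }
    } else {
      function(th) .mixNegLogLik(th, points)
    }
    ## warm starts: previous best model plus one fresh component makes the
    ## sweep incremental and keeps RSS monotone in n
    init <- NULL
    if (!is.null(prevPar) && length(prevPar) == npar * (n - 1L)) {
      nSeed <- max(8L, popFactor * 2L)
      init <- t(.withSeed(seed + 11L * n, replicate(nSeed, c(
        prevPar, stats::runif(npar, lo1, up1)))))
    }
    de <- diffEvolution(obj, lower, upper, popSize = popFactor * npar * n,
                        maxIter = maxIter, seed = seed + 97L * n,
                        init = init)
    pol <- tryCatch(
      stats::optim(de$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 600)),
      error = function(e) NULL)
    par <- if (!is.null(pol) && pol$value <= de$value) pol$par else de$par
    val <- min(de$value, if (is.null(pol)) Inf else pol$value)
    k <- 6L * n
    aic <- if (objective == "surface") N * log(val / N) + 2 * k
           else 2 * val + 2 * k
    fits[[as.character(n)]] <- list(par = par, rss = val, aic = aic, n = n)
    aicRows[[length(aicRows) + 1L]] <- data.frame(n = n, rss = val, aic = aic)
    prevPar <- par
  }
  if (!length(fits)) stop("all mixture fits failed")
  tab <- do.call(rbind, aicRows)
  best <- min(tab$aic)
  nSel <- min(tab$n[tab$aic <= best + deltaAIC])
  sel <- fits[[as.character(nSel)]]
  if (objective == "surface") {
    shp <- matrix(sel$par, ncol = 5, byrow = TRUE)
    A <- .mixBasis(sel$par, gx, gy)
    amp <- .nnlsAmplitudes(A, zv)
    comp <- as.data.frame(cbind(shp, amp))
  } else {
    comp <- as.data.frame(matrix(sel$par, ncol = 6, byrow = TRUE))
  }
  names(comp) <- c("mu1", "mu2", "sigma1", "sigma2", "rho", "a")
  comp$sigma1 <- abs(comp$sigma1); comp$sigma2 <- abs(comp$sigma2)
  model <- new("PopulationModel", components = comp, aic = sel$aic,
               aicTable = tab, shares = rep(NA_real_, nrow(comp)),
               significant = rep(NA, nrow(comp)), minShare = minShare,
               objective = objective)
  significanceFilter(model, minShare)
}

## Negative log-likelihood of a scaled-Gaussian mixture on raw points;
## weights are the normalised component volumes.
.mixNegLogLik <- function(theta, points) {
  n <- length(theta) / 6L
  vol <- numeric(n)
  dens <- matrix(0, nrow(points), n)
  for (k in seq_len(n)) {
    p <- theta[(6 * (k - 1) + 1):(6 * k)]
    s1 <- p[3]; s2 <- p[4]; rho <- p[5]; a <- p[6]
    om <- 1 - rho^2
    vol[k] <- a * 2 * pi * s1 * s2 * sqrt(om)
    u <- (points[, 1] - p[1]) / s1
    v <- (points[, 2] - p[2]) / s2
    q <- (u^2 - 2 * rho * u * v + v^2) / om
    dens[, k] <- exp(-q / 2) / (2 * pi * s1 * s2 * sqrt(om))
  }
  if (sum(vol) <= 0) return(1e10)
  w <- vol / sum(vol)
  ll <- log(pmax(dens %*% w, 1e-300))
  -sum(ll)
}

#' Flag significant components by PDF-volume share
#'
#' Each component's volume is a 2 pi sigma1 sigma2 sqrt(1 - rho^2); its
#' share is the fraction of the summed volume. Components with share below
#' \code{minShare} are flagged non-significant.
#'
#' @param model a \linkS4class{PopulationModel}.
#' @param minShare significance threshold on the volume share.
#' @return The model with shares and significance flags filled in.
#' @export
significanceFilter <- function(model, minShare = 0.05) {
  stopifnot(is(model, "PopulationModel"))
  cc <- model@components
  vol <- cc$a * 2 * pi * cc$sigma1 * cc$sigma2 * sqrt(1 - cc$rho^2)
  shares <- if (sum(vol) > 0) vol / sum(vol) else rep(0, length(vol))
  model@shares <- shares
  model@significant <- shares >= minShare
  model@minShare <- minShare
  model
}

#' Error-weighted critical-radius fit
#'
#' Weighted least squares of moment on radius with weights 1/sigma_m^2;
#' the critical radius r_c = -b0/b1 (the radius where the fitted moment
#' crosses zero) with a delta-method standard error. A non-positive slope
#' leaves r_c undefined (NA).
#'
#' @param R effective radii, um.
#' @param m magnetic moments (any consistent unit).
#' @param sigmaM per-point moment uncertainties (> 0).
#' @return A \linkS4class{CriticalRadiusFit}.
#' @examples
#' R <- seq(0.6, 1.2, length.out = 20)
#' criticalRadius(R, 5 * (R - 0.57), rep(0.1, 20))
#' @export
criticalRadius <- function(R, m, sigmaM) {
  .stopIfNot(length(R) >= 3L, "need at least 3 points")
  .checkPositive(sigmaM, "sigmaM")
  fit <- stats::lm(m ~ R, weights = 1 / sigmaM^2)
  cf <- summary(fit)$coefficients
  b0 <- cf[1, 1]; b1 <- cf[2, 1]
  V <- stats::vcov(fit)
  if (b1 <= 0) {
    rc <- NA_real_; rcSE <- NA_real_
  } else {
    rc <- -b0 / b1
    grad <- c(-1 / b1, b0 / b1^2)
    rcSE <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  new("CriticalRadiusFit", slope = c(b1, cf[2, 2]),
      intercept = c(b0, cf[1, 2]), rc = rc, rcSE = rcSE, fit = fit)
}

## Douglas-Peucker simplification of an open polyline (keeps endpoints).
.douglasPeucker <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- rep(FALSE, n); keep[c(1, n)] <- TRUE
  recurse <- function(i, j) {
    if (j <= i + 1L) return()
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    d <- if (len == 0) sqrt(rowSums(sweep(pts[(i + 1):(j - 1), , drop = FALSE],
                                          2, a)^2))
    else abs((pts[(i + 1):(j - 1), 1] - a[1]) * ab[2] -
             (pts[(i + 1):(j - 1), 2] - a[2]) * ab[1]) / len
    k <- which.max(d)
    if (d[k] > tol) {
      mid <- i + k
      keep[mid] <<- TRUE
      recurse(i, mid); recurse(mid, j)
    }
  }
  recurse(1L, n)
  pts[keep, , drop = FALSE]
}

#' Directional quantile envelope
#'
#' For \code{nDirections} evenly spaced unit vectors u, computes the
#' q-quantile of the projections <x - centre, u> and intersects the
#' half-planes \{<x - centre, u> <= t_u\} (Sutherland-Hodgman clipping of a
#' bounding box). The resulting convex polygon is simplified by
#' Douglas-Peucker.
#'
#' @param points n x 2 matrix (n >= 20).
#' @param q quantile level (default 0.95).
#' @param nDirections number of directions (default 250).
#' @param simplifyTol Douglas-Peucker tolerance as a fraction of the
#'   envelope's mean radius (0 keeps all vertices).
#' @return A \linkS4class{QuantileEnvelope}; vertices form a closed polygon.
#' @export
quantileEnvelope <- function(points, q = 0.95, nDirections = 250L,
                             simplifyTol = 0.002) {
  points <- as.matrix(points)
  .stopIfNot(nrow(points) >= 20L, "need at least 20 points")
  .stopIfNot(q > 0 && q <= 1, "q must be in (0, 1]")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  ang <- 2 * pi * (seq_len(nDirections) - 1) / nDirections
  U <- cbind(cos(ang), sin(ang))
  tq <- vapply(seq_len(nDirections), function(i) {
    pr <- cen %*% U[i, ]
    as.numeric(stats::quantile(pr, q, type = 7))
  }, numeric(1))

  ## start from a generous box and clip by each half-plane <p, u> <= t
  big <- max(abs(cen)) * 4 + max(abs(tq)) * 4 + 1
  poly <- matrix(c(-big, -big, big, -big, big, big, -big, big), ncol = 2,
                 byrow = TRUE)
  clip <- function(poly, u, t) {
    n <- nrow(poly)
    if (n == 0L) return(poly)
    out <- list()
    d <- poly %*% u - t
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      di <- d[i]; dj <- d[j]
      if (di <= 0) out[[length(out) + 1L]] <- poly[i, ]
      if ((di < 0) != (dj < 0) && di != dj) {
        s <- di / (di - dj)
        out[[length(out) + 1L]] <- poly[i, ] + s * (poly[j, ] - poly[i, ])
      }
    }
    if (!length(out)) return(matrix(numeric(0), 0, 2))
    do.call(rbind, out)
  }
  for (i in seq_len(nDirections)) poly <- clip(poly, U[i, ], tq[i])
  if (!nrow(poly)) stop("empty envelope (q too small for the data)")
  poly <- sweep(poly, 2, ctr, "+")

  if (simplifyTol > 0 && nrow(poly) > 4L) {
    mr <- mean(sqrt(rowSums(sweep(poly, 2, ctr)^2)))
    ## split the ring at its two extreme-x vertices so endpoints are kept
    iMin <- which.min(poly[, 1]);
    poly2 <- rbind(poly[iMin:nrow(poly), , drop = FALSE],
                   poly[seq_len(iMin), , drop = FALSE])
    poly <- .douglasPeucker(poly2, simplifyTol * mr)
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  closed <- rbind(poly, poly[1, ])
  colnames(closed) <- c("x", "y")
  new("QuantileEnvelope", q = q, nDirections = as.integer(nDirections),
      vertices = closed, centre = ctr)
}
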