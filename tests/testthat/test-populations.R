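test_that("kernel density surface is a proper density close to the truth", {
  set.seed(15)
  pts <- cbind(rnorm(10000), rnorm(10000))
  d <- kde2d(pts)
  dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
  expect_equal(sum(d$z) * dx * dy, 1, tolerance = 1e-3)
  # L1 distance to the true standard-normal density below 0.1
  true <- outer(dnorm(d$x), dnorm(d$y))
  expect_lt(sum(abs(d$z - true)) * dx * dy, 0.1)
  # tight cluster: mode within one grid cell of the sample mean
  tight <- cbind(rnorm(500, 3, 0.05), rnorm(500, -1, 0.05))
  dt <- kde2d(tight)
  idx <- which(dt$z == max(dt$z), arr.ind = TRUE)
  expect_lt(abs(dt$x[idx[1]] - mean(tight[, 1])), 3 * diff(dt$x[1:2]))
  expect_lt(abs(dt$y[idx[2]] - mean(tight[, 2])), 3 * diff(dt$y[1:2]))
  expect_error(kde2d(cbind(rep(1, 20), rnorm(20))), "degenerate")
})

test_that("differential evolution finds smooth optima deterministically", {
  sphere <- function(p) sum((p - c(1, -2, 0.5))^2)
  r1 <- diffEvolution(sphere, rep(-5, 3), rep(5, 3), seed = 16,
                      maxIter = 150)
  expect_equal(r1$par, c(1, -2, 0.5), tolerance = 1e-3)
  r2 <- diffEvolution(sphere, rep(-5, 3), rep(5, 3), seed = 16,
                      maxIter = 150)
  expect_identical(r1, r2)
})

test_that("single-population surfaces keep one significant component", {
  comp <- data.frame(mu1 = 1.4, mu2 = 0.6, sigma1 = 0.2, sigma2 = 0.1,
                     rho = 0.3)
  nsig <- vapply(1:3, function(s) {
    pts <- sampleMixture(comp, 60000, seed = s)
    m <- fitMixtureSweep(pts, nRange = 1:3, seed = s + 50, gridSize = 48,
                         popFactor = 8, maxIter = 100)
    # dominant component parameters recovered within 5 %
    cc <- nearestComponent(m, 1.4, 0.6)
    expect_equal(cc$mu1, 1.4, tolerance = 0.05)
    expect_equal(cc$mu2, 0.6, tolerance = 0.05)
    expect_equal(cc$sigma1, 0.2, tolerance = 0.2)
    sum(isSignificant(m))
  }, numeric(1))
  expect_true(all(nsig == 1))
})

test_that("two well-separated populations are both recovered", {
  comp <- data.frame(mu1 = c(0, 3), mu2 = c(0, 2), sigma1 = 0.5,
                     sigma2 = 0.4, rho = 0)
  pts <- sampleMixture(comp, 15000, seed = 17)
  m <- fitMixtureSweep(pts, nRange = 1:3, seed = 18, gridSize = 48,
                       popFactor = 8, maxIter = 100)
  expect_equal(sum(isSignificant(m)), 2)
  expect_equal(sort(mixtureComponents(m)$mu1[isSignificant(m)]), c(0, 3),
               tolerance = 0.1)
})

test_that("volume shares are normalised and zero-amplitude components drop", {
  comp <- data.frame(mu1 = c(0, 1), mu2 = c(0, 1), sigma1 = c(1, 1),
                     sigma2 = c(1, 1), rho = c(0, 0), a = c(2, 2))
  model <- new("PopulationModel", components = comp, aic = 0,
               aicTable = data.frame(n = 2, rss = 0, aic = 0),
               shares = rep(NA_real_, 2), significant = rep(NA, 2),
               minShare = 0.05, objective = "surface")
  model <- significanceFilter(model)
  expect_equal(volumeShares(model), c(0.5, 0.5))
  comp$a <- c(3, 0)
  model@components <- comp
  model <- significanceFilter(model)
  expect_equal(volumeShares(model), c(1, 0))
  expect_identical(isSignificant(model), c(TRUE, FALSE))
  expect_equal(sum(volumeShares(model)), 1)
})

test_that("critical radius fit is exact on a line and unbiased under noise", {
  R <- seq(0.6, 1.2, length.out = 30)
  cr <- criticalRadius(R, 5 * (R - 0.57), rep(0.1, 30))
  expect_equal(criticalRadiusValue(cr), 0.57, tolerance = 1e-10)
  # equal weights reduce to ordinary least squares
  set.seed(19)
  m <- 5 * (R - 0.57) + rnorm(30, 0, 0.2)
  cw <- criticalRadius(R, m, rep(0.3, 30))
  ols <- lm(m ~ R)
  expect_equal(cw@slope[1], unname(coef(ols)[2]), tolerance = 1e-10)
  # bias below the standard error across seeds
  res <- vapply(1:60, function(s) {
    set.seed(s)
    mm <- 5 * (R - 0.57) + rnorm(30, 0, 0.15)
    f <- criticalRadius(R, mm, rep(0.15, 30))
    c(f@rc, f@rcSE)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.57), mean(res[2, ]))
  # non-positive slope: r_c undefined
  down <- criticalRadius(R, 5 * (0.57 - R), rep(0.1, 30))
  expect_true(is.na(criticalRadiusValue(down)))
})

test_that("directional quantile envelopes match the Gaussian analytic circle", {
  set.seed(20)
  pts <- cbind(rnorm(20000), rnorm(20000))
  env <- quantileEnvelope(pts, q = 0.95, nDirections = 250)
  rad <- sqrt(rowSums(sweep(envelopeVertices(env), 2, env@centre)^2))
  expect_equal(mean(rad), qnorm(0.95), tolerance = 0.05)
  expect_lt(diff(range(rad)) / qnorm(0.95), 0.1)
  # rotation equivariance
  a <- 0.6; Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  envR <- quantileEnvelope(pts %*% t(Rm), q = 0.95, nDirections = 250)
  radR <- sqrt(rowSums(sweep(envelopeVertices(envR), 2, envR@centre)^2))
  expect_equal(mean(radR), mean(rad), tolerance = 0.01)
  # q = 1 envelope contains the convex hull (all points inside)
  small <- cbind(rnorm(200), rnorm(200))
  env1 <- quantileEnvelope(small, q = 1, nDirections = 120,
                           simplifyTol = 0)
  vv <- envelopeVertices(env1)
  ctr <- env1@centre
  inside <- vapply(seq_len(nrow(small)), function(i) {
    p <- small[i, ] - ctr
    all(vapply(seq_len(nrow(vv) - 1L), function(j) {
      a <- vv[j, ] - ctr; b <- vv[j + 1L, ] - ctr
      ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) >=
        -1e-9 * max(abs(c(a, b)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(inside))
})
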