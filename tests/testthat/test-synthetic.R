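test_that("mixture sampling reproduces component moments and respects seeds", {
  comp <- day1Components()
  s <- sampleMixture(comp, 60000, seed = 3)
  lab <- attr(s, "component")
  for (k in 1:4) {
    pts <- s[lab == k, ]
    n <- nrow(pts)
    mc <- 4 / sqrt(n)  # Monte-Carlo slack on means/sds
    expect_equal(mean(pts[, 1]), comp$mu1[k], tolerance = mc)
    expect_equal(mean(pts[, 2]), comp$mu2[k], tolerance = mc)
    expect_equal(sd(pts[, 1]), comp$sigma1[k], tolerance = 5 * mc)
    expect_equal(sd(pts[, 2]), comp$sigma2[k], tolerance = 5 * mc)
    expect_equal(cor(pts[, 1], pts[, 2]), comp$rho[k], tolerance = 8 * mc)
  }
  # bit-identical under the same seed
  expect_identical(sampleMixture(comp, 1000, seed = 5),
                   sampleMixture(comp, 1000, seed = 5))
  # zero-weight component never drawn
  comp2 <- day2Components(); comp2$weight <- c(1, 0)
  s2 <- sampleMixture(comp2, 2000, seed = 6)
  expect_true(all(attr(s2, "component") == 1L))
})

test_that("population sampler assigns moments by the linear size law", {
  spec <- populationSpec(data.frame(mu1 = 1.3, mu2 = 0.7, sigma1 = 0.15,
                                    sigma2 = 0.12, rho = 0),
                         momentModel = list(type = "linear", slope = 5e-15,
                                            rc = 0.57))
  cells <- samplePopulation(spec, 4000, seed = 7)
  expect_equal(cells$m_Am2, pmax(5e-15 * (cells$R_um - 0.57), 0))
  expect_true(all(cells$v_um_s > 0))
  expect_equal(cells$v_um_s, 10^cells$log10_v)
})

test_that("U-turn datasets carry a consistent closed-form ground truth", {
  spec <- populationSpec(data.frame(mu1 = 1.35, mu2 = 0.75, sigma1 = 0.08,
                                    sigma2 = 0.05, rho = 0),
                         momentModel = list(type = "gaussian",
                                            mean = 1.5e-15, sd = 2e-16))
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4))
  gen <- genUturnDataset(spec, fp, nCells = 5, dt = 0.01, seed = 8)
  expect_equal(nTracks(gen$tracks), 5)
  expect_equal(nrow(gen$truth), 5)
  # noise-free measured asymptotic width matches L_theory within 1 %
  # (only turns much shorter than the half-period have fully developed)
  d <- trackData(gen$tracks)
  for (i in gen$truth$cell_id) {
    tau <- gen$truth$L_theory_um[i] / (pi * gen$truth$v_um_s[i])
    if (16 * tau > 2) next
    tr <- d[d$track_id == i, ]
    leg <- tr[tr$t_s >= 2 & tr$t_s < 4, ]
    pre <- tr[tr$t_s < 2, ]
    ## lateral displacement in the frame of the incoming leg
    ang <- atan2(pre$y_um[nrow(pre)] - pre$y_um[1],
                 pre$x_um[nrow(pre)] - pre$x_um[1])
    lat <- -(leg$x_um - leg$x_um[1]) * sin(ang) +
      (leg$y_um - leg$y_um[1]) * cos(ang)
    expect_equal(abs(lat[length(lat)]), gen$truth$L_theory_um[i],
                 tolerance = 0.01)
  }
  # m = 0 cells: no reversal response (net displacement keeps growing)
  spec0 <- populationSpec(data.frame(mu1 = 1.3, mu2 = 0.7, sigma1 = 0.05,
                                     sigma2 = 0.05, rho = 0),
                          momentModel = list(type = "gaussian", mean = 0,
                                             sd = 0))
  gen0 <- genUturnDataset(spec0, fp, nCells = 2, dt = 0.02, seed = 9)
  expect_equal(length(segmentUturns(
    trackData(gen0$tracks)[trackData(gen0$tracks)$track_id == 1, ], fp)), 0)
})

test_that("rendering is deterministic, centroid-faithful and nuisance-robust", {
  d <- data.frame(track_id = 1, frame = 0, t_s = 0, x_um = 10.3, y_um = 8.7,
                  area_um2 = pi * 0.6^2)
  ts <- trackSet(d, pixelSize = 0.25)
  spec <- renderSpec(width = 192, height = 192, pixelSize = 0.25)
  r <- renderStack(ts, spec, seed = 2)
  # noise-free centroid of an isolated spot within 0.1 px of ground truth
  fr <- r$stack[, , 1]
  w <- fr - min(fr)
  ix <- rep(0:(nrow(w) - 1), ncol(w)); iy <- rep(0:(ncol(w) - 1), each = nrow(w))
  cx <- sum(ix * w) / sum(w); cy <- sum(iy * w) / sum(w)
  expect_lt(abs(cx - r$truth$x_px), 0.1)
  expect_lt(abs(cy - r$truth$y_px), 0.1)
  # identical seeds -> identical stacks (with noise on)
  specN <- renderSpec(width = 96, height = 96, pixelSize = 0.25,
                      gaussianNoise = 0.03, poissonNoise = TRUE)
  r1 <- renderStack(ts, specN, seed = 4)
  r2 <- renderStack(ts, specN, seed = 4)
  expect_identical(r1$stack, r2$stack)
  # gradient is nuisance only: ground truth unchanged
  specG <- renderSpec(width = 96, height = 96, pixelSize = 0.25,
                      gradientAmplitude = 0.2)
  expect_equal(renderStack(ts, specG, seed = 5)$truth, r1$truth)
  # static cell, no noise: frames identical
  d2 <- rbind(d, transform(d, frame = 1, t_s = 0.02))
  r3 <- renderStack(trackSet(d2, pixelSize = 0.25), spec, seed = 6)
  expect_identical(r3$stack[, , 1], r3$stack[, , 2])
  expect_error(renderStack(trackSet(d[0, ], pixelSize = 0.25), spec), "empty")
})
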