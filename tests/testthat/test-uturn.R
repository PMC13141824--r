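test_that("segmentation yields one candidate per reversal and drops m = 0", {
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4, 6))
  tr <- simulateTrajectory(cellState(speed = 25, moment = 1.5e-15), fp,
                           dt = 0.01, duration = 8)
  segs <- segmentUturns(trackData(tr), fp)
  expect_equal(length(segs), 3)
  # static protocol: nothing to segment
  expect_equal(length(segmentUturns(trackData(tr),
                                    fieldProtocol(mode = "static"))), 0)
  tr0 <- simulateTrajectory(cellState(speed = 25, moment = 0), fp,
                            dt = 0.01, duration = 8)
  expect_equal(length(segmentUturns(trackData(tr0), fp)), 0)
})

test_that("fallback reversal detection agrees with the protocol", {
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4))
  tr <- simulateTrajectory(cellState(speed = 25, moment = 1.5e-15,
                                     radius = 0.7), fp, dt = 0.01,
                           duration = 6)
  withProto <- segmentUturns(trackData(tr), fp)
  noProto <- segmentUturns(trackData(tr), NULL)
  expect_equal(length(noProto), length(withProto))
  # the detected boundary can only lag the field flip by the heading
  # response time; it must never precede it, and the fitted widths of the
  # two segmentations must agree
  for (i in seq_along(withProto)) {
    lag <- attr(noProto[[i]], "reversalTime") -
      attr(withProto[[i]], "reversalTime")
    expect_gte(lag, 0)
    f1 <- fitUturnWidth(canonicalizeSegment(withProto[[i]]))
    f2 <- fitUturnWidth(canonicalizeSegment(noProto[[i]]))
    expect_true(f1@converged && f2@converged)
    expect_equal(uturnWidth(f2), uturnWidth(f1), tolerance = 0.02)
  }
})

test_that("canonical form matches the theoretical shape and is rigid-invariant", {
  cs <- cellState(speed = 25, moment = 1.5e-15, radius = 0.7)
  tau <- relaxationTime(cs, 2.55e-4)
  Lth <- pi * 25 * tau
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = 2)
  tr <- simulateTrajectory(cs, fp, dt = 0.005, duration = 4)
  seg <- segmentUturns(trackData(tr), fp)[[1]]
  can <- canonicalizeSegment(seg)
  inside <- abs(can[, 1]) < 0.49 * Lth
  # perpendicular distance to the theoretical arc (a vertical gap on the
  # near-vertical legs overstates the geometric mismatch)
  u <- pi * can[inside, 1] / Lth
  dev <- abs(can[inside, 2] - uturnShape(can[inside, 1], Lth)) * cos(u)
  expect_lt(max(dev), 0.001 * Lth)
  # invariance under a rigid motion of the input
  a <- 0.83; Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  rot <- as.matrix(seg[, c("x_um", "y_um")]) %*% t(Rm)
  seg2 <- seg
  seg2$x_um <- rot[, 1] + 11.3; seg2$y_um <- rot[, 2] - 4.2
  attr(seg2, "preHeading") <- attr(seg, "preHeading") + a
  can2 <- canonicalizeSegment(seg2)
  expect_equal(can2, can, tolerance = 1e-8)
  # straight-line segment is degenerate along one axis after rotation
  straight <- data.frame(x_um = rep(0, 20), y_um = seq(0, 10, length.out = 20))
  attr(straight, "preHeading") <- pi / 2
  canS <- canonicalizeSegment(straight)
  fitS <- fitUturnWidth(canS)
  expect_false(fitS@converged)
})

test_that("width fitting is exact on clean samples and rejects non-U-turns", {
  x <- seq(-4.9, 4.9, length.out = 60)
  fit <- fitUturnWidth(cbind(x, uturnShape(x, 10)))
  expect_true(fit@converged)
  expect_equal(uturnWidth(fit), 10, tolerance = 1e-6)
  # Gaussian position noise sigma = 0.1 um on an L = 10 um turn: median
  # relative width error over seeds below 5 %
  errs <- vapply(1:7, function(s) {
    set.seed(s)
    pts <- cbind(x + rnorm(60, 0, 0.1), uturnShape(x, 10) + rnorm(60, 0, 0.1))
    f <- fitUturnWidth(pts, uturnParams(residualThreshold = 0.2))
    abs(uturnWidth(f) - 10) / 10
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  # a circular arc is not a U-turn: high residual, rejected
  th <- seq(0, pi, length.out = 50)
  arc <- cbind(5 * cos(th), 5 * sin(th) - 5)
  expect_false(fitUturnWidth(arc)@converged)
})

test_that("moment recovery hits ground truth and exclusion logic holds", {
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(2, 4))
  cs <- cellState(speed = 25, moment = 1.5e-15, radius = 0.7)
  tr <- simulateTrajectory(cs, fp, dt = 0.01, duration = 6)
  me <- estimateMoments(tr, fp)
  est <- momentTable(me)
  expect_equal(nrow(est), 1)
  expect_equal(est$m_Am2, 1.5e-15, tolerance = 0.02)
  expect_equal(est$n_uturns, 2)
  # two U-turns with identical L: track moment equals the per-turn moment
  expect_equal(est$m_Am2,
               momentFromUturn(est$L_um, est$v_um_s, est$R_um), tolerance = 0.02)
  # m = 0 track excluded with the non-magnetic reason code
  tr0 <- simulateTrajectory(cellState(speed = 25, moment = 0), fp,
                            dt = 0.01, duration = 6)
  me0 <- estimateMoments(tr0, fp)
  expect_equal(nrow(momentTable(me0)), 0)
  expect_equal(excludedTracks(me0)$reason, "non-magnetic or unfit")
})

test_that("noise-free recovery stays under 2 % across the (m, v, R) grid", {
  for (m in c(1e-16, 1e-15, 1e-14)) for (v in c(5, 50)) for (R in c(0.3, 1.2)) {
    cs <- cellState(speed = v, moment = m, radius = R)
    tau <- relaxationTime(cs, 2.55e-4)
    fp <- fieldProtocol(mode = "square_wave", reversalTimes = 2 * tau)
    tr <- simulateTrajectory(cs, fp, dt = tau / 60, duration = 18 * tau)
    est <- momentTable(estimateMoments(tr, fp,
                                       params = uturnParams(maxWidth = Inf)))
    expect_equal(est$m_Am2, m, tolerance = 0.02)
  }
})

test_that("larger moments produce tighter turns at fixed v, R, B", {
  Ls <- vapply(c(5e-16, 1e-15, 2e-15, 4e-15), function(m) {
    cs <- cellState(speed = 20, moment = m, radius = 0.6)
    tau <- relaxationTime(cs, 2.55e-4)
    fp <- fieldProtocol(mode = "square_wave", reversalTimes = 2 * tau)
    tr <- simulateTrajectory(cs, fp, dt = tau / 60, duration = 18 * tau)
    momentTable(estimateMoments(tr, fp))$L_um
  }, numeric(1))
  expect_true(all(diff(Ls) < 0))
})
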