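test_that("rotational drag follows the cubic law in both conventions", {
  # hand evaluation: 8 pi^2 * 0.9e-3 * (1e-6)^3
  expect_equal(rotationalDrag(1, 0.90e-3), 7.106115e-20, tolerance = 1e-5)
  expect_equal(rotationalDrag(1) / rotationalDrag(1, convention = "sphere"),
               pi, tolerance = 1e-12)
  # cubic: R -> 0 sends alpha -> 0
  expect_lt(rotationalDrag(1e-4), 1e-30)
  expect_equal(rotationalDrag(2) / rotationalDrag(1), 8, tolerance = 1e-12)
  expect_error(rotationalDrag(-1), "R")
  expect_error(rotationalDrag(1, eta = 0), "eta")
})

test_that("effective radius inverts the equal-area circle", {
  expect_equal(effectiveRadius(pi), 1)
  expect_equal(effectiveRadius(pi / 4), 0.5)
  expect_equal(effectiveRadius(1), sqrt(1 / pi), tolerance = 1e-12)
  expect_error(effectiveRadius(0))
})

test_that("U-turn shape is even, zero at apex, divergent at the legs", {
  expect_equal(uturnShape(0, 7), 0)
  expect_equal(uturnShape(2.5, 10), -(10 / pi) * log(sqrt(2)),
               tolerance = 1e-12)
  x <- seq(0.1, 4.9, by = 0.2)
  expect_equal(uturnShape(x, 10), uturnShape(-x, 10))
  y <- uturnShape(seq(4.0, 4.999, length.out = 50), 10)
  expect_true(all(diff(y) < 0))
  expect_lt(min(y), -5)
  expect_error(uturnShape(5, 10), "defined")
})

test_that("moment formula is the algebraic inverse of the width relation", {
  # SI identity: alpha = v = B = L = 1 -> m = pi, checked via unit scaling
  expect_equal(momentFromUturn(30, 30, 1, B = 2.55e-4, eta = 0.90e-3),
               8.754713e-16, tolerance = 1e-5)
  # substitute L = pi v alpha / (m B) back and recover m exactly
  m0 <- 1.5e-15; v <- 22; R <- 0.7; B <- 2.55e-4
  alpha <- rotationalDrag(R)
  L <- pi * v * alpha / (m0 * B)  # v, L in um keeps units consistent
  expect_equal(momentFromUturn(L, v, R, B), m0, tolerance = 1e-12)
  # homogeneity: m ~ v, ~ 1/L, ~ R^3
  expect_equal(momentFromUturn(10, 40, 1) / momentFromUturn(10, 20, 1), 2)
  expect_equal(momentFromUturn(20, 20, 1) / momentFromUturn(10, 20, 1), 0.5)
  expect_equal(momentFromUturn(10, 20, 2) / momentFromUturn(10, 20, 1), 8)
  expect_error(momentFromUturn(0, 1, 1))
})

test_that("simulated heading matches the closed-form relaxation", {
  cs <- cellState(heading = pi - 1e-3, speed = 30, moment = 1.5e-15,
                  radius = 0.7)
  tau <- relaxationTime(cs, 2.55e-4)
  tr <- simulateTrajectory(cs, fieldProtocol(mode = "static"),
                           dt = tau / 200, duration = 5 * tau)
  th <- attr(tr, "heading")
  cf <- headingClosedForm(trackData(tr)$t_s, pi - 1e-3, tau)
  expect_lt(max(abs(th - cf)), 1e-9)
})

test_that("simulator conserves speed and zero moment gives a straight line", {
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = c(1, 2))
  tr <- simulateTrajectory(cellState(speed = 25, moment = 1.5e-15), fp,
                           dt = 0.01, duration = 3)
  d <- trackData(tr)
  step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2) / diff(d$t_s)
  expect_equal(step, rep(25, length(step)), tolerance = 1e-9)
  # m = 0: no torque, straight line
  tr0 <- simulateTrajectory(cellState(speed = 25, moment = 0, heading = 0.4),
                            fp, dt = 0.01, duration = 3)
  d0 <- trackData(tr0)[-1, ]  # skip the origin (0/0)
  expect_equal(d0$y_um / d0$x_um, rep(tan(0.4), nrow(d0)), tolerance = 1e-9)
})

test_that("asymptotic lateral displacement across a reversal equals pi v tau", {
  cs <- cellState(speed = 30, moment = 2e-15, radius = 0.8)
  tau <- relaxationTime(cs, 2.55e-4)
  fp <- fieldProtocol(mode = "square_wave", reversalTimes = tau)
  tr <- simulateTrajectory(cs, fp, dt = tau / 100, duration = 17 * tau)
  d <- trackData(tr)
  L <- abs(d$y_um[nrow(d)] - d$y_um[1])
  expect_equal(L, pi * 30 * tau, tolerance = 0.01)
})
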