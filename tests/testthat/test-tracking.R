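test_that("assignment solver matches brute-force enumeration", {
  set.seed(5)
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, matrix(setdiff(seq_len(n), k)[p], nrow(p)))))
  }
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    sol <- solveAssignment(cost)
    got <- sum(cost[cbind(seq_len(n), sol)])
    pp <- perms(n)
    best <- min(apply(pp, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
    expect_equal(got, best, tolerance = 1e-12)
  }
  # rectangular: every row assigned to a distinct column
  cost <- matrix(runif(12), 3, 4)
  sol <- solveAssignment(cost)
  expect_equal(length(unique(sol)), 3)
})

test_that("prediction is exact for uniform motion and gated sensibly", {
  pts <- data.frame(t_s = (0:5) / 10, x_um = (0:5) * 2, y_um = (0:5) * -1)
  pr <- predictPosition(pts, 0.1, vMax = 50, slack = 2)
  expect_equal(pr$position, c(12, -6))
  expect_equal(pr$gate, 50 * 0.1 + 2)
  one <- data.frame(t_s = 0, x_um = 3, y_um = 4)
  pr1 <- predictPosition(one, 0.1, vMax = 50, slack = 2)
  expect_equal(pr1$position, c(3, 4))
})

test_that("tracker reconstructs non-interacting cells perfectly", {
  d <- linearTracks(8, frames = 25, seed = 21)
  det <- data.frame(frame = d$frame, x_px = d$x_um / 0.25,
                    y_px = d$y_um / 0.25, area_px2 = d$area_um2 / 0.25^2)
  tr <- buildTracks(det, fps = 50, pixelSize = 0.25,
                    trackingParams(vMax = 60, minTrackLength = 10))
  expect_equal(nTracks(tr), 8)
  truth <- data.frame(frame = d$frame, cell_id = d$track_id,
                      x_px = d$x_um / 0.25, y_px = d$y_um / 0.25)
  aa <- associationAccuracy(tr, truth, 0.25)
  expect_equal(aa$accuracy, 1)
  # deterministic: identical inputs give identical tracks
  tr2 <- buildTracks(det, fps = 50, pixelSize = 0.25,
                     trackingParams(vMax = 60, minTrackLength = 10))
  expect_identical(trackData(tr), trackData(tr2))
})

test_that("anti-parallel crossing cells keep their identities", {
  fr <- 0:20; t <- fr / 50
  a <- data.frame(frame = fr, t_s = t, x_um = 5 + 30 * t, y_um = 20 + 0.4,
                  area_um2 = 1)
  b <- data.frame(frame = fr, t_s = t, x_um = 17 - 30 * t, y_um = 20 - 0.4,
                  area_um2 = 1)
  det <- rbind(
    data.frame(frame = fr, x_px = a$x_um / 0.25, y_px = a$y_um / 0.25,
               area_px2 = 16),
    data.frame(frame = fr, x_px = b$x_um / 0.25, y_px = b$y_um / 0.25,
               area_px2 = 16))
  tr <- buildTracks(det, fps = 50, pixelSize = 0.25,
                    trackingParams(vMax = 60, minTrackLength = 10))
  expect_equal(nTracks(tr), 2)
  d <- trackData(tr)
  for (id in trackIds(tr)) {
    xx <- d$x_um[d$track_id == id]
    # velocity-aware cost: each track keeps moving one way through the cross
    expect_true(all(diff(xx) > 0) || all(diff(xx) < 0))
  }
})

test_that("single-frame dropouts are bridged and short tracks dropped", {
  d <- linearTracks(1, frames = 20, seed = 31)
  det <- data.frame(frame = d$frame, x_px = d$x_um / 0.25,
                    y_px = d$y_um / 0.25, area_px2 = 16)
  detGap <- det[det$frame != 10, ]
  tr <- buildTracks(detGap, fps = 50, pixelSize = 0.25,
                    trackingParams(vMax = 60, maxGap = 1, minTrackLength = 5))
  expect_equal(nTracks(tr), 1)
  trNoGap <- buildTracks(detGap, fps = 50, pixelSize = 0.25,
                         trackingParams(vMax = 60, maxGap = 0,
                                        minTrackLength = 5))
  expect_equal(nTracks(trNoGap), 2)
  # min_track_length = 5 removes 4-point tracks
  det4 <- det[det$frame < 4, ]
  tr4 <- buildTracks(det4, fps = 50, pixelSize = 0.25,
                     trackingParams(vMax = 60, minTrackLength = 5))
  expect_equal(nTracks(tr4), 0)
})
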