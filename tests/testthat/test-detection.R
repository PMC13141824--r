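test_that("illumination flattening removes constants and gradients", {
  cst <- matrix(0.4, 96, 96)
  expect_lt(max(abs(flattenIllumination(cst))), 1e-8)
  # pure linear gradient: residual amplitude < 5 % of input amplitude
  gr <- outer(seq(0, 0.3, length.out = 96), rep(1, 96))
  out <- flattenIllumination(gr)
  expect_lt(diff(range(out)), 0.05 * 0.3)
  # spot + gradient: spot contrast preserved within 10 %
  spot <- matrix(0, 96, 96)
  spot[40:44, 50:54] <- 0.5
  out2 <- flattenIllumination(gr + spot)
  expect_equal(max(out2), 0.5, tolerance = 0.1)
})

test_that("denoising improves salt-and-pepper PSNR and is nearly idempotent", {
  set.seed(3)
  ## smooth scene: background plus a Gaussian blob
  g <- outer(exp(-(seq(-3, 3, length.out = 64))^2),
             exp(-(seq(-3, 3, length.out = 64))^2))
  clean <- 0.3 + 0.5 * g
  noisy <- clean
  idx <- sample(length(noisy), 160)
  noisy[idx] <- rep(c(0, 1), 80)
  den <- denoiseFrame(noisy)
  psnr <- function(a, b) -10 * log10(mean((a - b)^2))
  expect_gt(psnr(den, clean), psnr(noisy, clean))
  # the mean of an uncorrupted frame barely changes
  denClean <- denoiseFrame(clean)
  expect_lt(abs(mean(denClean) - mean(clean)) / mean(clean), 0.01)
  # near-idempotence on an already-denoised smooth frame
  den2 <- denoiseFrame(den)
  expect_lt(max(abs(den2 - den)), 0.02)
  # flat regions of a noise-free frame are untouched by the median filter
  # (up to the filter's internal intensity quantisation)
  expect_equal(denClean[1:10, 1:10], clean[1:10, 1:10], tolerance = 1e-3)
})

test_that("segmentation finds well-separated spots and applies the area filter", {
  expect_equal(nrow(segmentCells(matrix(0.2, 64, 64))), 0)
  d <- data.frame(track_id = 1:3, frame = 0, t_s = 0,
                  x_um = c(10, 30, 44), y_um = c(12, 40, 22),
                  area_um2 = pi * c(0.5, 0.7, 0.9)^2)
  r <- renderStack(trackSet(d, pixelSize = 0.25),
                   renderSpec(width = 224, height = 224, pixelSize = 0.25),
                   seed = 1)
  det <- segmentCells(flattenIllumination(r$stack[, , 1]), minArea = 3)
  expect_equal(nrow(det), 3)
  for (i in 1:3) {
    j <- which.min((det$x_px - r$truth$x_px[i])^2 +
                   (det$y_px - r$truth$y_px[i])^2)
    expect_lt(sqrt((det$x_px[j] - r$truth$x_px[i])^2 +
                   (det$y_px[j] - r$truth$y_px[i])^2), 0.5)
  }
  # a generous minArea removes everything
  expect_equal(nrow(segmentCells(flattenIllumination(r$stack[, , 1]),
                                 minArea = 5000)), 0)
})

test_that("temporal-median removal suppresses static content", {
  d <- data.frame(track_id = 1, frame = 0:19, t_s = (0:19) / 50,
                  x_um = 8 + 30 * (0:19) / 50, y_um = 24, area_um2 = pi * 0.6^2)
  ts <- trackSet(d, pixelSize = 0.25)
  spec <- renderSpec(width = 192, height = 192, pixelSize = 0.25,
                     stuckFraction = 3)  # 3 static nuisance cells
  r <- renderStack(ts, spec, seed = 11)
  det <- detectStack(r$stack, detectionParams(minArea = 3,
                                              temporalMedian = TRUE))
  # only the moving spot remains; static debris subtracted
  expect_true(all(table(det$frame) == 1))
  sc <- detectionScore(det, r$truth, maxDist = 3)
  expect_gt(sc$recall, 0.9)
  expect_gt(sc$precision, 0.95)
  # stack of identical frames: nothing left after median removal
  still <- r$stack
  for (j in seq_len(dim(still)[3])) still[, , j] <- r$stack[, , 1]
  detStill <- detectStack(still, detectionParams(minArea = 3,
                                                 temporalMedian = TRUE))
  expect_equal(nrow(detStill), 0)
})
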