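## Shared fixtures: published population parameter tables used as generator
## ground truth, and small synthetic builders.

day1Components <- function() {
  data.frame(mu1 = c(0.98, 1.348, 1.429, 0.806),
             mu2 = c(0.402, 0.5379, 0.686, 0.519),
             sigma1 = c(0.40, 0.223, 0.165, 0.26),
             sigma2 = c(0.081, 0.0247, 0.127, 0.167),
             rho = c(-0.49, 0.30, -0.046, 0.51))
}

day2Components <- function() {
  data.frame(mu1 = c(0.38, 0.288), mu2 = c(0.439, 0.751),
             sigma1 = c(0.49, 0.239), sigma2 = c(0.103, 0.265),
             rho = c(0.28, -0.16))
}

momentComponents <- function() {
  ## (m in 1e-15 A m^2, R in um)
  data.frame(mu1 = c(1.314, 1.63, 2.35), mu2 = c(0.784, 0.9017, 0.941),
             sigma1 = c(0.413, 0.49, 0.99), sigma2 = c(0.062, 0.0279, 0.099),
             rho = c(0.60, -0.26, 0.816))
}

## straight-line swimmer tracks inside a (W x H) um field of view
linearTracks <- function(n, frames = 30, fov = 64, fps = 50, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    sp <- stats::runif(1, 10, 40)
    x0 <- stats::runif(1, fov * 0.15, fov * 0.85)
    y0 <- stats::runif(1, fov * 0.15, fov * 0.85)
    fr <- 0:frames
    t <- fr / fps
    data.frame(track_id = i, frame = fr, t_s = t,
               x_um = x0 + sp * cos(ang) * t, y_um = y0 + sp * sin(ang) * t,
               area_um2 = pi * stats::runif(1, 0.4, 0.9)^2)
  }))
}

nearestComponent <- function(model, mu1, mu2, scale = c(1, 1)) {
  cc <- mixtureComponents(model)
  i <- which.min(((cc$mu1 - mu1) / scale[1])^2 + ((cc$mu2 - mu2) / scale[2])^2)
  cc[i, ]
}
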