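## Frame-level cell detection: illumination flattening, edge-preserving
## denoising, contrast boosting + Otsu segmentation, and stack-level
## processing with temporal-median removal of immobile objects. Image
## primitives come from EBImage; frames are numeric matrices in [0, 1]
## indexed [x, y] with 0-based pixel-centre coordinates reported outward.

#' Detection parameters
#'
#' @param minArea,maxArea connected-component area filter, px^2.
#' @param flattenMethod \code{"poly"} (least-squares polynomial background,
#'   robust to linear/quadratic illumination gradients) or \code{"gaussian"}
#'   (heavy Gaussian blur background, radius >> cell size).
#' @param flattenDegree polynomial degree for \code{"poly"}.
#' @param flattenSigma blur sigma in px for \code{"gaussian"}.
#' @param denoiseMethod \code{"median"}, \code{"bilateral"} (Gaussian blur
#'   stand-in at small sigma) or \code{"none"}.
#' @param denoiseSize median filter half-size, px.
#' @param contrast \code{"clahe"}, \code{"gamma"} or \code{"none"}.
#' @param gamma exponent for \code{"gamma"}.
#' @param thresholdOffset additive offset on the Otsu threshold.
#' @param temporalMedian remove immobile objects by subtracting the per-pixel
#'   temporal median before detection.
#' @param medianWindow number of frames (subsampled) used for the temporal
#'   median background.
#' @return list of class \code{"DetectionParams"}.
#' @export
detectionParams <- function(minArea = 4, maxArea = 2000,
                            flattenMethod = c("poly", "gaussian"),
                            flattenDegree = 2, flattenSigma = 25,
                            denoiseMethod = c("median", "bilateral", "none"),
                            denoiseSize = 1L,
                            contrast = c("gamma", "clahe", "none"),
                            gamma = 0.7, thresholdOffset = 0,
                            temporalMedian = FALSE, medianWindow = 51L) {
  flattenMethod <- match.arg(flattenMethod)
  denoiseMethod <- match.arg(denoiseMethod)
  contrast <- match.arg(contrast)
  structure(as.list(environment()), class = "DetectionParams")
}

.asFrame <- function(frame) {
  if (is(frame, "Image")) frame <- EBImage::imageData(frame)
  if (length(dim(frame)) != 2L)
    stop("expected a single 2D grayscale frame")
  frame
}

#' Remove large-scale illumination background
#'
#' Estimates the slowly varying background of a frame and subtracts it,
#' clamping the result at zero. The default polynomial estimator fits a
#' degree-d surface by least squares on a subsampled pixel grid (exact for
#' linear/quadratic illumination gradients); the alternative subtracts a
#' heavy Gaussian blur.
#'
#' @param frame 2D numeric matrix (or EBImage Image) in [0, 1].
#' @param method,degree,sigma see \code{\link{detectionParams}}.
#' @return Matrix of the same size, minimum >= 0.
#' @export
flattenIllumination <- function(frame, method = c("poly", "gaussian"),
                                degree = 2, sigma = 25) {
  frame <- .asFrame(frame)
  method <- match.arg(method)
  if (method == "poly") {
    W <- nrow(frame); H <- ncol(frame)
    sx <- unique(round(seq(1, W, length.out = min(W, 48))))
    sy <- unique(round(seq(1, H, length.out = min(H, 48))))
    sub <- frame[sx, sy]
    u <- (sx - 1) / max(W - 1, 1); v <- (sy - 1) / max(H - 1, 1)
    basis <- function(u, v) {
      out <- list(rep(1, length(u)))
      for (p in 1:degree) for (q in 0:p)
        out[[length(out) + 1L]] <- u^(p - q) * v^q
      do.call(cbind, out)
    }
    g <- expand.grid(u = u, v = v)
    X <- basis(g$u, g$v)
    ## robust to bright spots: one reweighting pass down-weighting positives
    cf <- stats::lm.fit(X, as.vector(sub))$coefficients
    res <- as.vector(sub) - as.vector(X %*% cf)
    w <- ifelse(res > 0, 0.1, 1)
    cf <- stats::lm.wfit(X, as.vector(sub), w)$coefficients
    gu <- (seq_len(W) - 1) / max(W - 1, 1)
    gv <- (seq_len(H) - 1) / max(H - 1, 1)
    gg <- expand.grid(u = gu, v = gv)
    bg <- matrix(basis(gg$u, gg$v) %*% cf, W, H)
  } else {
    bg <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame),
                                            sigma = sigma))
  }
  pmax(frame - bg, 0)
}

#' Edge-preserving denoising
#'
#' @param frame 2D numeric matrix in [0, 1].
#' @param method \code{"median"}, \code{"bilateral"} or \code{"none"}.
#' @param size filter half-size in px (median) or sigma (bilateral).
#' @return Denoised matrix of the same size.
#' @export
denoiseFrame <- function(frame, method = c("median", "bilateral", "none"),
                         size = 1L) {
  frame <- .asFrame(frame)
  method <- match.arg(method)
  if (method == "none") return(frame)
  img <- EBImage::Image(pmin(pmax(frame, 0), 1))
  out <- switch(method,
    median = EBImage::medianFilter(img, size = as.integer(size)),
    bilateral = EBImage::gblur(img, sigma = max(size, 0.8)))
  EBImage::imageData(out)
}

#' Segment cells in a single frame
#'
#' Contrast boosting (gamma or CLAHE) followed by a global Otsu threshold,
#' connected-component labelling and an area filter. Because Otsu degrades
#' when foreground pixels are a tiny fraction of the frame, the threshold
#' is floored at a robust noise level (median + 6 * MAD of the boosted
#' frame). Centroids are
#' intensity-weighted over each component. The reported area is the
#' component's half-peak (FWHM) area -- the number of pixels at or above
#' half its peak intensity -- which is far less threshold-dependent than
#' the raw mask size and near-unbiased for smooth symmetric spots; the
#' area filter, by contrast, applies to the raw mask size.
#'
#' @param frame preprocessed 2D matrix in [0, 1].
#' @param minArea,maxArea area filter bounds, px^2.
#' @param contrast \code{"gamma"}, \code{"clahe"} or \code{"none"}.
#' @param gamma gamma exponent.
#' @param thresholdOffset additive offset applied to the Otsu threshold.
#' @return data.frame(x_px, y_px, area_px2, mean_intensity), 0-based pixel
#'   coordinates; empty (zero rows) on an all-background frame.
#' @export
segmentCells <- function(frame, minArea = 4, maxArea = 2000,
                         contrast = c("gamma", "clahe", "none"),
                         gamma = 0.7, thresholdOffset = 0) {
  frame <- .asFrame(frame)
  contrast <- match.arg(contrast)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px2 = numeric(0), mean_intensity = numeric(0))
  rng <- range(frame)
  if (diff(rng) < 1e-6) return(empty)
  norm <- (frame - rng[1]) / diff(rng)
  boosted <- switch(contrast,
    gamma = norm^gamma,
    clahe = EBImage::imageData(EBImage::clahe(EBImage::Image(norm))),
    none = norm)
  ## noise floor: Otsu is unreliable when cells cover a tiny area fraction.
  ## The floor is estimated on the un-boosted frame (contrast boosts are
  ## nonlinear and would inflate a robust scale estimate).
  floorTh <- stats::median(norm) + 6 * stats::mad(norm)
  th <- EBImage::otsu(EBImage::Image(boosted)) + thresholdOffset
  mask <- boosted > th & norm > floorTh
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  labv <- as.vector(EBImage::imageData(lab))
  keepPx <- labv > 0
  if (!any(keepPx)) return(empty)
  W <- nrow(frame)
  idx <- which(keepPx)
  lv <- labv[idx]
  ix <- (idx - 1L) %% W          # 0-based x
  iy <- (idx - 1L) %/% W         # 0-based y
  wgt <- as.vector(frame)[idx]
  lv <- factor(lv, levels = seq_len(max(lv)))
  maskArea <- tabulate(lv)
  sw <- vapply(split(wgt, lv), sum, numeric(1))
  cx <- vapply(split(wgt * ix, lv), sum, numeric(1)) / sw
  cy <- vapply(split(wgt * iy, lv), sum, numeric(1)) / sw
  mi <- sw / maskArea
  ## half-peak (FWHM) area per component
  pk <- vapply(split(wgt, lv), max, numeric(1))
  fwhmArea <- vapply(seq_along(pk), function(k) {
    sum(split(wgt, lv)[[k]] >= pk[k] / 2)
  }, numeric(1))
  keep <- maskArea >= minArea & maskArea <= maxArea & sw > 0
  data.frame(x_px = cx[keep], y_px = cy[keep], area_px2 = fwhmArea[keep],
             mean_intensity = mi[keep], row.names = NULL)
}

#' Detect cells across an image stack
#'
#' Applies temporal-median background removal (optional; suppresses stuck and
#' motionless cells and static debris), illumination flattening, denoising
#' and segmentation frame by frame. A frame whose processing fails is logged
#' and skipped.
#'
#' @param stack numeric array width x height x frames in [0, 1] (or an
#'   EBImage Image).
#' @param params a \code{\link{detectionParams}} list.
#' @return data.frame(frame, x_px, y_px, area_px2, mean_intensity) with
#'   0-based frame indices; attribute \code{"skipped"} lists skipped frames.
#' @export
detectStack <- function(stack, params = detectionParams()) {
  if (is(stack, "Image")) stack <- EBImage::imageData(stack)
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  .stopIfNot(length(dim(stack)) == 3L, "stack must be a 3D grayscale array")
  nf <- dim(stack)[3]
  bg <- NULL
  if (isTRUE(params$temporalMedian)) {
    pick <- unique(round(seq(1, nf, length.out = min(nf, params$medianWindow))))
    bg <- apply(stack[, , pick, drop = FALSE], c(1, 2), stats::median)
  }
  out <- vector("list", nf)
  skipped <- integer(0)
  for (j in seq_len(nf)) {
    det <- tryCatch({
      fr <- stack[, , j]
      if (!is.null(bg)) fr <- pmax(fr - bg, 0)
      fr <- flattenIllumination(fr, params$flattenMethod,
                                params$flattenDegree, params$flattenSigma)
      fr <- denoiseFrame(fr, params$denoiseMethod, params$denoiseSize)
      segmentCells(fr, params$minArea, params$maxArea, params$contrast,
                   params$gamma, params$thresholdOffset)
    }, error = function(e) {
      warning(sprintf("frame %d skipped: %s", j - 1L, conditionMessage(e)))
      NULL
    })
    if (is.null(det)) { skipped <- c(skipped, j - 1L); next }
    if (nrow(det)) out[[j]] <- cbind(frame = j - 1L, det)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px2 = numeric(0),
                      mean_intensity = numeric(0))
  attr(res, "skipped") <- skipped
  res
}

#' Score detections against ground truth
#'
#' Greedy nearest matching per frame within a distance gate; reports
#' precision and recall.
#'
#' @param detections data.frame(frame, x_px, y_px, ...).
#' @param truth data.frame(frame, x_px, y_px, ...) of true centroids.
#' @param maxDist matching gate in px.
#' @return list(precision, recall, meanError_px, nMatched).
#' @export
detectionScore <- function(detections, truth, maxDist = 3) {
  tp <- 0L; errs <- numeric(0)
  for (f in unique(truth$frame)) {
    tt <- truth[truth$frame == f, ]
    dd <- detections[detections$frame == f, ]
    if (!nrow(dd)) next
    D <- outer(tt$x_px, dd$x_px, "-")^2 + outer(tt$y_px, dd$y_px, "-")^2
    D <- sqrt(D)
    while (length(D) && min(D) <= maxDist) {
      k <- arrayInd(which.min(D), dim(D))
      tp <- tp + 1L
      errs <- c(errs, D[k])
      D[k[1], ] <- Inf
      D[, k[2]] <- Inf
    }
  }
  list(precision = if (nrow(detections)) tp / nrow(detections) else NA_real_,
       recall = if (nrow(truth)) tp / nrow(truth) else NA_real_,
       meanError_px = if (length(errs)) mean(errs) else NA_real_,
       nMatched = tp)
}
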