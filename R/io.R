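## Formats: multi-page grayscale TIFF stacks (EBImage) and the tracks CSV
## interchange format (track_id, frame, t_s, x_um, y_um, area_um2), which
## external trackers can also produce. CSV dialect: comma separated, UTF-8,
## '.' decimal, units embedded in column names.

#' Read a grayscale image stack
#'
#' @param path a multi-page grayscale TIFF file.
#' @return numeric array width x height x frames in [0, 1].
#' @export
readStack <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or empty stack file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable stack file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (EBImage::colorMode(img) != EBImage::Grayscale)
    stop("RGB input not supported; convert to grayscale first ",
         "(e.g. EBImage::channel(img, 'gray'))")
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  .stopIfNot(length(dim(a)) == 3L, "mixed frame shapes are not supported")
  a
}

#' Write a grayscale image stack
#'
#' @param stack numeric array width x height x frames in [0, 1].
#' @param path output TIFF path.
#' @param bits bit depth (8 or 16).
#' @return path, invisibly.
#' @export
writeStack <- function(stack, path, bits = 16) {
  .stopIfNot(bits %in% c(8, 16), "bits must be 8 or 16")
  img <- EBImage::Image(pmin(pmax(stack, 0), 1))
  EBImage::writeImage(img, path, type = "tiff", bits.per.sample = bits)
  invisible(path)
}

.TRACK_COLS <- c("track_id", "frame", "t_s", "x_um", "y_um", "area_um2")

#' Read a tracks CSV
#'
#' @param path CSV with header track_id, frame, t_s, x_um, y_um, area_um2
#'   (extra columns are kept). Rows may be in any order; duplicated
#'   (track_id, frame) pairs are fatal.
#' @param pixelSize,frameRate optional metadata to attach.
#' @return A \linkS4class{TrackSet}.
#' @export
readTracks <- function(path, pixelSize = NA_real_, frameRate = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path))
  miss <- setdiff(.TRACK_COLS, names(d))
  if (length(miss))
    stop("tracks file is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d[, c("track_id", "frame")]))
    stop("duplicate (track_id, frame) rows in ", path)
  trackSet(d, pixelSize = pixelSize, frameRate = frameRate)
}

#' Write a tracks CSV
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  stopifnot(is(tracks, "TrackSet"))
  data.table::fwrite(trackData(tracks), path)
  invisible(path)
}

#' Default run configuration
#'
#' Nested configuration for the end-to-end pipeline; any part can be
#' overridden via YAML (\code{\link{readConfig}}) or by list surgery. Every
#' run writes the resolved configuration alongside its outputs.
#'
#' @param pixelSize pixel scale, um/px.
#' @param frameRate frame rate, Hz.
#' @param seed run seed.
#' @return Nested list of class \code{"RunConfig"}.
#' @export
defaultConfig <- function(pixelSize = 0.25, frameRate = 50, seed = 1) {
  structure(list(
    pixelSize = pixelSize,
    frameRate = frameRate,
    seed = seed,
    field = list(magnitude = 2.55e-4, axis = c(1, 0), mode = "static",
                 reversalTimes = numeric(0)),
    medium = list(viscosity = 0.90e-3),
    dragConvention = "pisq",
    detection = unclass(detectionParams()),
    tracking = unclass(trackingParams()),
    uturn = unclass(uturnParams()),
    velocimetry = list(passiveThreshold = 7, complianceFilter = FALSE,
                       complianceToleranceDeg = 30),
    populations = list(nRange = 1:4, gridSize = 64, minShare = 0.05,
                       popFactor = 15, maxIter = 250)
  ), class = "RunConfig")
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file.
#' @return A \code{"RunConfig"} list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultConfig()
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  structure(merge2(unclass(base), user), class = "RunConfig")
}

.fieldFromConfig <- function(cfg) {
  fieldProtocol(magnitude = cfg$field$magnitude, axis = cfg$field$axis,
                mode = cfg$field$mode,
                reversalTimes = cfg$field$reversalTimes)
}

#' Run the end-to-end pipeline
#'
#' detect -> track -> velocimetry and, when the protocol is square-wave,
#' U-turn moment estimation -> population decomposition. Stage-wise counts,
#' the resolved configuration and the seed are recorded in a JSON manifest;
#' outputs are CSV/JSON files in \code{outDir}. Inputs are never modified.
#'
#' @param stack image stack array, or a path readable by
#'   \code{\link{readStack}}.
#' @param config a \code{"RunConfig"} (see \code{\link{defaultConfig}}).
#' @param outDir output directory (created if needed).
#' @param populationsOn which axes to decompose: \code{"velocimetry"}
#'   ((log10 v, R) samples) and/or \code{"moments"} ((m, R) estimates);
#'   stages without enough data are skipped with a note.
#' @return Invisible list with the main results (detections, tracks,
#'   samples, moments, models, manifest).
#' @export
runPipeline <- function(stack, config = defaultConfig(), outDir = tempfile(),
                        populationsOn = "velocimetry") {
  if (is.character(stack)) stack <- readStack(stack)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "magnetokinetics",
                   version = as.character(utils::packageVersion("magnetokinetics")),
                   seed = config$seed, stages = list())
  field <- .fieldFromConfig(config)

  detPar <- do.call(detectionParams, config$detection[names(config$detection)
    %in% names(formals(detectionParams))])
  det <- detectStack(stack, detPar)
  manifest$stages$detection <- list(frames = dim(stack)[3],
                                    detections = nrow(det),
                                    skipped = attr(det, "skipped"))
  data.table::fwrite(det, file.path(outDir, "detections.csv"))

  trkPar <- do.call(trackingParams, config$tracking[names(config$tracking)
    %in% names(formals(trackingParams))])
  tracks <- buildTracks(det, config$frameRate, config$pixelSize, trkPar)
  manifest$stages$tracking <- list(inDetections = nrow(det),
                                   tracks = nTracks(tracks),
                                   points = nrow(trackData(tracks)))
  writeTracks(tracks, file.path(outDir, "tracks.csv"))

  samples <- velocimetrySamples(tracks)
  if (isTRUE(config$velocimetry$complianceFilter)) {
    tracksV <- mfComplianceFilter(tracks, -field@axis,
                                  config$velocimetry$complianceToleranceDeg)
    samples <- velocimetrySamples(tracksV)
  }
  samples$passive <- passiveFlag(samples$v_um_s,
                                 config$velocimetry$passiveThreshold)
  manifest$stages$velocimetry <- list(samples = nrow(samples))
  data.table::fwrite(samples, file.path(outDir, "velocimetry_samples.csv"))

  moments <- NULL
  if (field@mode == "square_wave") {
    upar <- do.call(uturnParams, config$uturn[names(config$uturn) %in%
                                              names(formals(uturnParams))])
    moments <- estimateMoments(tracks, field,
                               mediumParams(config$medium$viscosity), upar,
                               convention = config$dragConvention)
    manifest$stages$uturn <- list(tracksIn = nTracks(tracks),
                                  estimated = nrow(momentTable(moments)),
                                  excluded = nrow(excludedTracks(moments)))
    data.table::fwrite(momentTable(moments), file.path(outDir, "moments.csv"))
  }

  models <- list()
  pcfg <- config$populations
  if ("velocimetry" %in% populationsOn && nrow(samples) >= 50) {
    pts <- cbind(log10(samples$v_um_s[samples$v_um_s > 0]),
                 samples$R_um[samples$v_um_s > 0])
    models$velocimetry <- fitMixtureSweep(
      pts, nRange = pcfg$nRange, seed = config$seed,
      gridSize = pcfg$gridSize, popFactor = pcfg$popFactor,
      maxIter = pcfg$maxIter, minShare = pcfg$minShare)
  }
  if ("moments" %in% populationsOn && !is.null(moments) &&
      nrow(momentTable(moments)) >= 50) {
    mt <- momentTable(moments)
    models$moments <- fitMixtureSweep(
      cbind(mt$m_Am2 * 1e15, mt$R_um), nRange = pcfg$nRange,
      seed = config$seed, gridSize = pcfg$gridSize,
      popFactor = pcfg$popFactor, maxIter = pcfg$maxIter,
      minShare = pcfg$minShare)
  }
  if (length(models)) {
    toList <- function(m) list(components = m@components,
                               aic = m@aic, shares = m@shares,
                               significant = m@significant)
    jsonlite::write_json(lapply(models, toList),
                         file.path(outDir, "populations.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(detections = det, tracks = tracks, samples = samples,
                 moments = moments, models = models, manifest = manifest,
                 outDir = outDir))
}
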