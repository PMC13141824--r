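#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("momentTable", function(x) standardGeneric("momentTable"))

#' @rdname accessors
#' @export
setGeneric("excludedTracks", function(x) standardGeneric("excludedTracks"))

#' @rdname accessors
#' @export
setGeneric("mixtureComponents", function(x) standardGeneric("mixtureComponents"))

#' @rdname accessors
#' @export
setGeneric("volumeShares", function(x) standardGeneric("volumeShares"))

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname accessors
#' @export
setGeneric("aicTable", function(x) standardGeneric("aicTable"))

#' @rdname accessors
#' @export
setGeneric("uturnWidth", function(x) standardGeneric("uturnWidth"))

#' @rdname accessors
#' @export
setGeneric("envelopeVertices", function(x) standardGeneric("envelopeVertices"))

#' @rdname accessors
#' @export
setGeneric("criticalRadiusValue", function(x) standardGeneric("criticalRadiusValue"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("trackData", "TrackSet", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("trackIds", "TrackSet", function(x) unique(x@data$track_id))

#' @rdname accessors
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@data$track_id)))

#' @rdname accessors
#' @export
setMethod("momentTable", "MomentEstimates", function(x) x@estimates)

#' @rdname accessors
#' @export
setMethod("excludedTracks", "MomentEstimates", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("mixtureComponents", "PopulationModel", function(x) x@components)

#' @rdname accessors
#' @export
setMethod("volumeShares", "PopulationModel", function(x) x@shares)

#' @rdname accessors
#' @export
setMethod("isSignificant", "PopulationModel", function(x) x@significant)

#' @rdname accessors
#' @export
setMethod("aicTable", "PopulationModel", function(x) x@aicTable)

#' @rdname accessors
#' @export
setMethod("uturnWidth", "UTurnFit", function(x) x@width)

#' @rdname accessors
#' @export
setMethod("envelopeVertices", "QuantileEnvelope", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("criticalRadiusValue", "CriticalRadiusFit", function(x) x@rc)

## ---- show ----------------------------------------------------------------

setMethod("show", "FieldProtocol", function(object) {
  cat(sprintf("FieldProtocol: %s, B = %.3g T, axis = (%.3f, %.3f)\n",
              object@mode, object@magnitude, object@axis[1], object@axis[2]))
  if (length(object@reversalTimes))
    cat(sprintf("  %d reversals in [%.3g, %.3g] s\n",
                length(object@reversalTimes), min(object@reversalTimes),
                max(object@reversalTimes)))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks, %d points", nTracks(object),
              nrow(object@data)))
  if (!is.na(object@frameRate))
    cat(sprintf(", %g fps", object@frameRate))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %g um/px", object@pixelSize))
  cat("\n")
})

setMethod("show", "UTurnFit", function(object) {
  cat(sprintf("UTurnFit: L = %.3g um, residual = %.3g, n = %d, %s\n",
              object@width, object@residual, object@nPoints,
              if (object@converged) "converged" else "rejected"))
})

setMethod("show", "MomentEstimates", function(object) {
  cat(sprintf("MomentEstimates: %d tracks with moments, %d excluded\n",
              nrow(object@estimates), nrow(object@excluded)))
  if (nrow(object@estimates)) {
    m <- object@estimates$m_Am2
    cat(sprintf("  m: median %.3g A m^2, range [%.3g, %.3g]\n",
                stats::median(m), min(m), max(m)))
  }
})

setMethod("show", "PopulationModel", function(object) {
  cat(sprintf("PopulationModel (%s fit): %d components, AIC = %.2f\n",
              object@objective, nrow(object@components), object@aic))
  cc <- cbind(object@components,
              share = round(object@shares, 3),
              significant = object@significant)
  print(format(cc, digits = 4))
})

setMethod("show", "CriticalRadiusFit", function(object) {
  cat(sprintf("CriticalRadiusFit: r_c = %.4g um (SE %.3g), slope = %.3g (SE %.3g)\n",
              object@rc, object@rcSE, object@slope[1], object@slope[2]))
})

setMethod("show", "QuantileEnvelope", function(object) {
  cat(sprintf("QuantileEnvelope: q = %.3f, %d directions, %d vertices\n",
              object@q, object@nDirections, nrow(object@vertices) - 1L))
})
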