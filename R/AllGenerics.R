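#' @rdname CTSlice-class
#' @param x,object an object.
#' @export
setGeneric("hu", function(x) standardGeneric("hu"))

#' @rdname CTSlice-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname CTSlice-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname CTSlice-class
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))

#' @rdname CTSlice-class
#' @export
setGeneric("sliceLabel", function(x) standardGeneric("sliceLabel"))

#' @rdname HFMap-class
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname HFMap-class
#' @export
setGeneric("mapParamsOf", function(x) standardGeneric("mapParamsOf"))

#' Slice-level feature: the maximum of the HF map
#'
#' @param x an \linkS4class{HFMap}.
#' @return scalar; 0 for an all-zero map.
#' @export
setGeneric("sliceFeature", function(x) standardGeneric("sliceFeature"))

#' @export
#' @rdname CTSlice-class
setMethod("hu", "CTSlice", function(x) x@hu)

#' @export
#' @rdname CTSlice-class
setMethod("spacing", "CTSlice", function(x) x@spacing)

#' @export
#' @rdname CTSlice-class
setMethod("patientId", "CTSlice", function(x) x@patientId)

#' @export
#' @rdname CTSlice-class
setMethod("sliceId", "CTSlice", function(x) x@sliceId)

#' @export
#' @rdname CTSlice-class
setMethod("sliceLabel", "CTSlice", function(x) x@label)

#' @export
#' @rdname HFMap-class
setMethod("mapValues", "HFMap", function(x) x@values)

#' @export
#' @rdname HFMap-class
setMethod("mapParamsOf", "HFMap", function(x) x@params)

#' @export
#' @rdname HFMap-class
setMethod("sliceFeature", "HFMap", function(x) {
  if (length(x@values) == 0) return(0)
  max(x@values)
})

#' @rdname HomologyProfile-class
#' @param x a \linkS4class{HomologyProfile}.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
#' @rdname HomologyProfile-class
setMethod("thresholds", "HomologyProfile", function(x) x@thresholds)

#' @rdname HomologyProfile-class
#' @param index \code{"b0"} or \code{"b1"}.
#' @export
setGeneric("bettiCurve", function(x, index = "b0") standardGeneric("bettiCurve"))

#' @export
#' @rdname HomologyProfile-class
setMethod("bettiCurve", "HomologyProfile", function(x, index = "b0") {
  stopifnot(index %in% c("b0", "b1"))
  x@betti[, if (index == "b0") 1L else 2L]
})

#' @export
#' @rdname HomologyProfile-class
#' @param row.names,optional,... passed on conventions of \code{as.data.frame}.
setMethod("as.data.frame", "HomologyProfile",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(threshold = x@thresholds, b0 = x@betti[, 1L], b1 = x@betti[, 2L])
})

setMethod("show", "CTSlice", function(object) {
  cat(sprintf("CTSlice %s (patient %s, label %s): %d x %d px, %.3g x %.3g mm, HU [%g, %g]\n",
              object@sliceId, object@patientId, object@label,
              nrow(object@hu), ncol(object@hu), object@spacing[1],
              object@spacing[2], min(object@hu), max(object@hu)))
})

setMethod("show", "HomologyProfile", function(object) {
  n <- length(object@thresholds)
  if (n == 0) {
    cat("HomologyProfile: empty (no valid pixel in tile)\n")
  } else {
    cat(sprintf("HomologyProfile: %d thresholds in [%g, %g] HU; max b0 = %d, max b1 = %d\n",
                n, object@thresholds[1], object@thresholds[n],
                max(object@betti[, 1]), max(object@betti[, 2])))
  }
})

setMethod("show", "HFMap", function(object) {
  cat(sprintf("HFMap (%s, %s/%s) %d x %d px: feature (max) = %.4g; tiles %d kept / %d skipped\n",
              object@sliceId, object@params@index, object@params@mode,
              nrow(object@values), ncol(object@values), sliceFeature(object),
              object@tilesTotal - object@tilesSkipped, object@tilesSkipped))
})

setMethod("show", "MapParams", function(object) {
  cat(sprintf("MapParams: tile %d, shift %d, skip > %.2f, %s, index %s, mode %s; sweep [%g, %g] step %g HU (%s)\n",
              object@tileSize, object@shift, object@skipFraction,
              object@standardization, object@index, object@mode,
              object@profile@thresholdLo, object@profile@thresholdHi,
              object@profile@thresholdStep, object@profile@polarity))
})
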