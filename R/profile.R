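## Homology profile of a tile: binarize the HU raster at every threshold of
## the sweep and record the Betti pair.

#' Thresholds of a profile sweep
#'
#' Sequence from \code{thresholdLo} to \code{thresholdHi} in steps of
#' \code{thresholdStep}; when the step does not divide the range the final
#' threshold is clipped to \code{thresholdHi}.
#'
#' @param params a \linkS4class{ProfileParams}.
#' @return numeric vector of HU thresholds, strictly increasing.
#' @export
sweepThresholds <- function(params) {
  t <- seq(params@thresholdLo, params@thresholdHi, by = params@thresholdStep)
  if (t[length(t)] < params@thresholdHi) t <- c(t, params@thresholdHi)
  t
}

#' Binarize a tile at one threshold
#'
#' Foreground is the set of in-mask pixels satisfying the polarity predicate
#' (HU >= t by default, HU <= t for \code{polarity = "le"}); pixels outside
#' the mask are always background, so masked-out areas never create
#' components or close holes.
#'
#' @param tileHu numeric HU matrix.
#' @param tileMask logical matrix, same shape; \code{TRUE} = valid pixel.
#' @param t threshold (HU).
#' @param params a \linkS4class{ProfileParams}.
#' @return logical matrix.
#' @export
binarizeTile <- function(tileHu, tileMask, t, params = profileParams()) {
  if (!identical(dim(tileHu), dim(tileMask)))
    stop("tileHu and tileMask must have identical shape")
  fg <- if (params@polarity == "ge") tileHu >= t else tileHu <= t
  fg & tileMask
}

#' Homology profile of a tile over the threshold sweep
#'
#' One Betti pair per sweep threshold, computed on the binarized tile. A
#' tile with no in-mask pixel yields the empty-profile signal (a zero-row
#' \linkS4class{HomologyProfile}), distinct from an all-zero profile.
#'
#' @inheritParams binarizeTile
#' @return a \linkS4class{HomologyProfile}.
#' @examples
#' tile <- matrix(-500, 8, 8)
#' p <- homologyProfile(tile, params = profileParams(thresholdStep = 100))
#' as.data.frame(p)  # b0 = 1 until the threshold passes -500
#' @export
homologyProfile <- function(tileHu, tileMask = NULL, params = profileParams()) {
  if (is.null(tileMask)) tileMask <- matrix(TRUE, nrow(tileHu), ncol(tileHu))
  if (!identical(dim(tileHu), dim(tileMask)))
    stop("tileHu and tileMask must have identical shape")
  if (!any(tileMask))
    return(new("HomologyProfile", thresholds = numeric(0),
               betti = matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("b0", "b1")))))
  t <- sweepThresholds(params)
  conn <- params@connectivity
  betti <- .cppProfile(tileHu, tileMask, t, params@polarity == "ge",
                       conn@foreground == 8L, conn@background == 8L)
  colnames(betti) <- c("b0", "b1")
  new("HomologyProfile", thresholds = t, betti = betti)
}

#' Scalar summary of a homology profile
#'
#' \code{mode = "max"}: maximum of the chosen Betti sequence (a count).
#' \code{mode = "argmax"}: the lowest threshold attaining that maximum (HU;
#' ties broken toward the lowest threshold).
#'
#' @param profile a \linkS4class{HomologyProfile}.
#' @param index \code{"b0"} or \code{"b1"}.
#' @param mode \code{"max"} or \code{"argmax"}.
#' @return scalar.
#' @export
summarizeProfile <- function(profile, index = c("b0", "b1"),
                             mode = c("max", "argmax")) {
  index <- match.arg(index); mode <- match.arg(mode)
  if (length(profile@thresholds) == 0)
    stop("cannot summarize an empty homology profile")
  curve <- bettiCurve(profile, index)
  if (mode == "max") max(curve)
  else profile@thresholds[which.max(curve)]
}
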