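## Tile-shifted HF-map computation: slide a tile across the slice, summarize
## each tile's homology profile, standardize, and sum the overlapping
## contributions on the pixel grid.

#' Tile origins for a sliding window
#'
#' Origins are \code{1, 1 + shift, 1 + 2 shift, ...} on each axis such that
#' the \code{tileSize} footprint lies fully inside the raster (no padding);
#' returned in row-major order (row varies slowest).
#'
#' @param shape integer vector \code{c(rows, cols)}.
#' @param tileSize,shift tile edge and stride, pixels.
#' @return integer matrix with columns \code{row}, \code{col} (1-based).
#' @examples
#' nrow(iterTiles(c(512, 512), 32, 8))  # 61 x 61 = 3721
#' @export
iterTiles <- function(shape, tileSize, shift) {
  stopifnot(length(shape) == 2, shift >= 1, shift <= tileSize)
  if (tileSize > min(shape)) stop("tileSize exceeds the raster dimensions")
  rows <- seq(1L, shape[1] - tileSize + 1L, by = as.integer(shift))
  cols <- seq(1L, shape[2] - tileSize + 1L, by = as.integer(shift))
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Skip rule for a tile
#'
#' A tile is skipped when the fraction of its pixels lying OUTSIDE the lung
#' mask is strictly greater than \code{skipFraction} (a tile exactly at the
#' boundary fraction is kept).
#'
#' @param tileMask logical matrix (TRUE = inside the lung mask).
#' @param skipFraction proportion in (0, 1].
#' @return logical: \code{TRUE} to skip.
#' @export
tileSkip <- function(tileMask, skipFraction = 0.95) {
  mean(!tileMask) > skipFraction
}

#' Standardize a profile summary
#'
#' \code{pixel_area}: divide by the pixel area in mm^2 (component counts per
#' physical area, removing the pixel-size dependence); \code{pixel_spacing}:
#' divide by the row spacing in mm (isotropic spacing assumed);
#' \code{tile_pixels}: divide by the number of in-mask tile pixels;
#' \code{none}: identity.
#'
#' @param raw non-negative profile summary.
#' @param standardization mode, see above.
#' @param spacing pixel spacing \code{c(row, col)} in mm.
#' @param tileValidPixels in-mask pixel count (required for
#'   \code{tile_pixels}).
#' @return scalar.
#' @export
standardizeSummary <- function(raw,
                               standardization = c("pixel_area", "pixel_spacing",
                                                   "tile_pixels", "none"),
                               spacing = c(1, 1), tileValidPixels = NULL) {
  standardization <- match.arg(standardization)
  stopifnot(raw >= 0)
  switch(standardization,
         pixel_area = raw / (spacing[1] * spacing[2]),
         pixel_spacing = raw / spacing[1],
         tile_pixels = {
           if (is.null(tileValidPixels) || tileValidPixels == 0)
             stop("tile_pixels standardization requires a positive in-mask pixel count")
           raw / tileValidPixels
         },
         none = raw)
}

#' Compute the homology-feature map of a slice
#'
#' For every non-skipped tile position, the tile's homology profile is
#' summarized (max or argmax of b0 or b1), standardized, and ADDED to every
#' pixel of the tile footprint; overlapping contributions are summed
#' exactly, with no coverage normalization. Pixels covered by no kept tile
#' stay 0. Deterministic for fixed inputs and parameters.
#'
#' @param slice a \linkS4class{CTSlice} or numeric HU matrix.
#' @param mask logical lung mask, same shape; \code{NULL} means all-inside.
#' @param params a \linkS4class{MapParams}.
#' @return an \linkS4class{HFMap}.
#' @examples
#' sl <- ctSlice(matrix(-500, 16, 16))
#' pp <- profileParams(thresholdStep = 100)
#' m <- computeHFMap(sl, params = mapParams(tileSize = 4, shift = 2,
#'                                          standardization = "none",
#'                                          profile = pp))
#' sliceFeature(m)  # 4: interior pixels are covered by four unit tiles
#' @export
computeHFMap <- function(slice, mask = NULL, params = mapParams()) {
  if (is.matrix(slice)) slice <- ctSlice(slice)
  huMat <- slice@hu
  shape <- dim(huMat)
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  if (!identical(dim(mask), shape)) stop("slice and mask shapes differ")
  acc <- matrix(0, shape[1], shape[2])
  origins <- iterTiles(shape, params@tileSize, params@shift)
  skipped <- 0L
  if (!any(mask)) {
    warning("lung mask is empty; HF map is all zero")
    return(new("HFMap", values = acc, params = params, spacing = slice@spacing,
               sliceId = slice@sliceId, tilesTotal = nrow(origins),
               tilesSkipped = nrow(origins)))
  }
  ts <- params@tileSize
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1L]; cc <- origins[i, 2L]
    rr <- r:(r + ts - 1L); ccr <- cc:(cc + ts - 1L)
    tileMask <- mask[rr, ccr, drop = FALSE]
    if (tileSkip(tileMask, params@skipFraction)) {
      skipped <- skipped + 1L
      next
    }
    prof <- homologyProfile(huMat[rr, ccr, drop = FALSE], tileMask,
                            params@profile)
    if (length(prof@thresholds) == 0) { # no valid pixel but not skipped
      skipped <- skipped + 1L
      next
    }
    raw <- summarizeProfile(prof, params@index, params@mode)
    val <- standardizeSummary(raw, params@standardization, slice@spacing,
                              tileValidPixels = sum(tileMask))
    acc[rr, ccr] <- acc[rr, ccr] + val
  }
  new("HFMap", values = acc, params = params, spacing = slice@spacing,
      sliceId = slice@sliceId, tilesTotal = nrow(origins),
      tilesSkipped = skipped)
}

#' Slice features for a cohort
#'
#' Runs the per-slice pipeline (lung segmentation unless ground-truth masks
#' are used, HF map, slice feature) over a generated or loaded cohort and
#' returns one feature record per slice.
#'
#' @param cohort a list as returned by \code{\link{generateCohort}} (fields
#'   \code{manifest}, \code{slices}, \code{masks}).
#' @param params a \linkS4class{MapParams}.
#' @param seg a \linkS4class{SegParams}, or \code{NULL} to use the cohort's
#'   ground-truth masks.
#' @return data.frame with columns \code{patientId}, \code{sliceId},
#'   \code{feature}, \code{label}.
#' @export
cohortFeatures <- function(cohort, params = mapParams(), seg = segParams()) {
  n <- length(cohort$slices)
  feats <- numeric(n)
  for (i in seq_len(n)) {
    sl <- cohort$slices[[i]]
    msk <- if (is.null(seg)) cohort$masks[[i]] else extractLungMask(sl, seg)
    feats[i] <- sliceFeature(computeHFMap(sl, msk, params))
  }
  data.frame(patientId = vapply(cohort$slices, patientId, character(1)),
             sliceId = vapply(cohort$slices, sliceId, character(1)),
             feature = feats,
             label = vapply(cohort$slices, sliceLabel, character(1)),
             stringsAsFactors = FALSE)
}
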