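## Lung-field segmentation: air threshold, border clearing, largest
## components, morphological closing, hole filling. Morphology is delegated
## to EBImage.

#' Extract the lung-field mask from a CT slice
#'
#' Thresholds the slice below \code{airThreshold} HU, removes components
#' touching the image border (air surrounding the body), keeps the
#' \code{keepComponents} largest remaining components (the lungs), applies
#' morphological closing with a disk of \code{closingRadius} pixels and
#' fills interior holes so vessels and solid nodules stay inside the lung
#' field. Deterministic.
#'
#' @param slice a \linkS4class{CTSlice} or numeric HU matrix.
#' @param params a \linkS4class{SegParams}.
#' @return logical mask matrix (TRUE = lung field); empty with a warning
#'   when no candidate component survives.
#' @export
extractLungMask <- function(slice, params = segParams()) {
  if (is.matrix(slice)) slice <- ctSlice(slice)
  huMat <- slice@hu
  air <- huMat <= params@airThreshold
  lab <- EBImage::bwlabel(air)
  if (max(lab) == 0) {
    warning("no air-density component found; lung mask is empty")
    return(matrix(FALSE, nrow(huMat), ncol(huMat)))
  }
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  keepIds <- setdiff(seq_len(max(lab)), border)
  if (length(keepIds) == 0) {
    warning("all air components touch the border; lung mask is empty")
    return(matrix(FALSE, nrow(huMat), ncol(huMat)))
  }
  sizes <- tabulate(lab[lab %in% keepIds], nbins = max(lab))
  keepIds <- keepIds[order(sizes[keepIds], decreasing = TRUE)]
  keepIds <- keepIds[seq_len(min(params@keepComponents, length(keepIds)))]
  m <- matrix(lab %in% keepIds, nrow(lab), ncol(lab))
  if (params@closingRadius > 0) {
    brush <- EBImage::makeBrush(2L * params@closingRadius + 1L, shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0
  }
  if (params@fillHoles) m <- EBImage::fillHull(m * 1) > 0
  matrix(m, nrow(huMat), ncol(huMat))
}

#' Extract the lung-field image
#'
#' Replaces HU outside the mask with \code{fill}. The HF-map computation
#' masks pixels explicitly, so the fill value is cosmetic (for exported
#' lung-field images); +100 HU keeps the surround visually soft-tissue-like.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param mask logical mask, same shape.
#' @param fill replacement HU for masked-out pixels.
#' @return a \linkS4class{CTSlice} with identical metadata.
#' @export
applyMask <- function(slice, mask, fill = 100) {
  if (is.matrix(slice)) slice <- ctSlice(slice)
  if (!identical(dim(mask), dim(slice@hu))) stop("slice and mask shapes differ")
  huMat <- slice@hu
  huMat[!mask] <- fill
  initialize(slice, hu = huMat)
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return 2|A n B| / (|A| + |B|); 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
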