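#' @useDynLib hfmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Binary images and lung masks are plain logical matrices (TRUE = foreground /
## lung field); the S4 layer is reserved for the containers that carry
## metadata: CTSlice, HomologyProfile, HFMap and the parameter objects.

setClassUnion("listOrNULL", c("list", "NULL"))

#' Connectivity convention for 2D cubical homology
#'
#' Pairs a foreground with a background adjacency (4 or 8). The two must
#' differ: using the same adjacency for both phases produces the classical
#' Jordan paradoxes where a closed curve fails to separate, or a non-closed
#' one separates, the plane. The default pairs 8-adjacency for foreground
#' with 4-adjacency for background.
#'
#' @slot foreground integer, 4 or 8.
#' @slot background integer, 4 or 8, different from \code{foreground}.
#' @export
setClass("ConnectivityRule",
         representation(foreground = "integer", background = "integer"),
         prototype(foreground = 8L, background = 4L))

setValidity("ConnectivityRule", function(object) {
  if (!object@foreground %in% c(4L, 8L) || !object@background %in% c(4L, 8L))
    return("adjacencies must be 4 or 8")
  if (object@foreground == object@background)
    return("foreground and background adjacency must differ (Jordan duality)")
  TRUE
})

#' @param foreground,background adjacency (4 or 8) for each phase.
#' @rdname ConnectivityRule-class
#' @export
connectivityRule <- function(foreground = 8, background = 4) {
  new("ConnectivityRule", foreground = as.integer(foreground),
      background = as.integer(background))
}

#' Parameters of the threshold sweep producing a homology profile
#'
#' The sweep runs from \code{thresholdLo} to \code{thresholdHi} in steps of
#' \code{thresholdStep} HU (the final threshold is clipped to
#' \code{thresholdHi} when the step does not divide the range). Polarity
#' \code{"ge"} takes pixels at or above the threshold as foreground --
#' fibrous tissue is denser than aerated lung, so in the default
#' -700..-400 HU window the foreground phase tracks fibrotic structure;
#' \code{"le"} selects the air phase instead.
#'
#' @slot thresholdLo,thresholdHi,thresholdStep sweep range and step in HU.
#' @slot polarity \code{"ge"} (foreground = HU >= t) or \code{"le"}.
#' @slot connectivity a \linkS4class{ConnectivityRule}.
#' @export
setClass("ProfileParams",
         representation(thresholdLo = "numeric", thresholdHi = "numeric",
                        thresholdStep = "numeric", polarity = "character",
                        connectivity = "ConnectivityRule"),
         prototype(thresholdLo = -700, thresholdHi = -400, thresholdStep = 1,
                   polarity = "ge", connectivity = new("ConnectivityRule")))

setValidity("ProfileParams", function(object) {
  if (object@thresholdLo > object@thresholdHi)
    return("thresholdLo must be <= thresholdHi")
  if (object@thresholdStep <= 0) return("thresholdStep must be > 0")
  if (!object@polarity %in% c("ge", "le"))
    return("polarity must be 'ge' or 'le'")
  TRUE
})

#' @param thresholdLo,thresholdHi,thresholdStep sweep range and step (HU).
#' @param polarity \code{"ge"} or \code{"le"}.
#' @param connectivity a \linkS4class{ConnectivityRule}.
#' @rdname ProfileParams-class
#' @export
profileParams <- function(thresholdLo = -700, thresholdHi = -400,
                          thresholdStep = 1, polarity = c("ge", "le"),
                          connectivity = connectivityRule()) {
  new("ProfileParams", thresholdLo = as.numeric(thresholdLo),
      thresholdHi = as.numeric(thresholdHi),
      thresholdStep = as.numeric(thresholdStep),
      polarity = match.arg(polarity), connectivity = connectivity)
}

#' Homology profile of a tile
#'
#' The ordered sequence of Betti pairs (b0, b1) recorded while the
#' binarization threshold sweeps the HU range. A zero-row profile is the
#' distinct signal for a tile with no valid (in-mask) pixel; it is not the
#' same as an all-zero profile.
#'
#' @slot thresholds strictly increasing HU thresholds.
#' @slot betti integer matrix, one row per threshold, columns \code{b0}, \code{b1}.
#' @export
setClass("HomologyProfile",
         representation(thresholds = "numeric", betti = "matrix"))

setValidity("HomologyProfile", function(object) {
  if (nrow(object@betti) != length(object@thresholds))
    return("betti must have one row per threshold")
  if (length(object@thresholds) > 1 && any(diff(object@thresholds) <= 0))
    return("thresholds must be strictly increasing")
  if (ncol(object@betti) != 2) return("betti must have columns b0, b1")
  if (length(object@betti) && any(object@betti < 0))
    return("Betti numbers are non-negative")
  TRUE
})

#' Parameters of the tile-shifted HF-map computation
#'
#' A \code{tileSize} x \code{tileSize} tile is shifted by \code{shift}
#' pixels across the slice; each tile's profile summary (max or argmax of
#' b0 or b1) is standardized and added to every pixel of the tile
#' footprint. Tiles whose fraction of pixels outside the lung mask is
#' strictly greater than \code{skipFraction} are skipped.
#'
#' @slot tileSize,shift tile edge and stride, pixels.
#' @slot skipFraction skip threshold on the outside-mask fraction, in (0, 1].
#' @slot standardization one of \code{"pixel_area"} (divide by the pixel area
#'   in mm^2), \code{"pixel_spacing"} (divide by the row spacing in mm),
#'   \code{"tile_pixels"} (divide by the in-mask pixel count) or \code{"none"}.
#' @slot profile a \linkS4class{ProfileParams}.
#' @slot index \code{"b0"} or \code{"b1"}.
#' @slot mode \code{"max"} or \code{"argmax"}.
#' @export
setClass("MapParams",
         representation(tileSize = "integer", shift = "integer",
                        skipFraction = "numeric", standardization = "character",
                        profile = "ProfileParams", index = "character",
                        mode = "character"),
         prototype(tileSize = 32L, shift = 8L, skipFraction = 0.95,
                   standardization = "pixel_area",
                   profile = new("ProfileParams"), index = "b0", mode = "max"))

setValidity("MapParams", function(object) {
  if (object@tileSize < 1L) return("tileSize must be >= 1")
  if (object@shift < 1L || object@shift > object@tileSize)
    return("shift must satisfy 1 <= shift <= tileSize")
  if (object@skipFraction <= 0 || object@skipFraction > 1)
    return("skipFraction must lie in (0, 1]")
  if (!object@standardization %in%
        c("pixel_area", "pixel_spacing", "tile_pixels", "none"))
    return("unknown standardization mode")
  if (!object@index %in% c("b0", "b1")) return("index must be 'b0' or 'b1'")
  if (!object@mode %in% c("max", "argmax")) return("mode must be 'max' or 'argmax'")
  TRUE
})

#' @param tileSize,shift tile edge and stride in pixels.
#' @param skipFraction skip threshold (fraction outside mask), in (0, 1].
#' @param standardization standardization mode, see slots.
#' @param profile a \linkS4class{ProfileParams}.
#' @param index Betti index used for the map.
#' @param mode profile summary mode.
#' @rdname MapParams-class
#' @export
mapParams <- function(tileSize = 32, shift = 8, skipFraction = 0.95,
                      standardization = c("pixel_area", "pixel_spacing",
                                          "tile_pixels", "none"),
                      profile = profileParams(),
                      index = c("b0", "b1"), mode = c("max", "argmax")) {
  new("MapParams", tileSize = as.integer(tileSize), shift = as.integer(shift),
      skipFraction = as.numeric(skipFraction),
      standardization = match.arg(standardization), profile = profile,
      index = match.arg(index), mode = match.arg(mode))
}

#' A CT slice in Hounsfield units
#'
#' @slot hu numeric matrix of Hounsfield units (finite).
#' @slot spacing pixel spacing in mm, \code{c(row, col)}, both > 0.
#' @slot patientId,sliceId identifiers.
#' @slot label one of \code{"fibrosis"}, \code{"non_fibrosis"},
#'   \code{"lung_cancer"}, \code{"unknown"}.
#' @export
setClass("CTSlice",
         representation(hu = "matrix", spacing = "numeric",
                        patientId = "character", sliceId = "character",
                        label = "character"),
         prototype(spacing = c(1, 1), patientId = NA_character_,
                   sliceId = NA_character_, label = "unknown"))

setValidity("CTSlice", function(object) {
  if (!is.numeric(object@hu)) return("hu must be a numeric matrix")
  if (nrow(object@hu) < 1 || ncol(object@hu) < 1) return("hu must be non-empty")
  if (!all(is.finite(object@hu))) return("HU values must be finite")
  if (length(object@spacing) != 2 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
    return("spacing must be two positive values (mm)")
  if (!object@label %in% c("fibrosis", "non_fibrosis", "lung_cancer", "unknown"))
    return("unknown label")
  TRUE
})

#' @param hu numeric HU matrix.
#' @param spacing pixel spacing in mm (length 1 or 2).
#' @param patientId,sliceId identifiers.
#' @param label slice label.
#' @rdname CTSlice-class
#' @export
ctSlice <- function(hu, spacing = c(1, 1), patientId = NA_character_,
                    sliceId = NA_character_, label = "unknown") {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  new("CTSlice", hu = hu, spacing = as.numeric(spacing),
      patientId = as.character(patientId), sliceId = as.character(sliceId),
      label = as.character(label))
}

#' Homology-feature map of a slice
#'
#' The accumulated, standardized per-tile profile maxima on the slice pixel
#' grid. Values are zero wherever no non-skipped tile covers the pixel.
#'
#' @slot values non-negative numeric matrix, same shape as the slice.
#' @slot params the \linkS4class{MapParams} used.
#' @slot spacing pixel spacing in mm.
#' @slot sliceId provenance identifier.
#' @slot tilesTotal,tilesSkipped tile bookkeeping for the skip rule.
#' @export
setClass("HFMap",
         representation(values = "matrix", params = "MapParams",
                        spacing = "numeric", sliceId = "character",
                        tilesTotal = "integer", tilesSkipped = "integer"))

setValidity("HFMap", function(object) {
  if (length(object@values) && any(object@values < 0))
    return("HF map values must be non-negative")
  if (object@tilesSkipped > object@tilesTotal)
    return("tilesSkipped cannot exceed tilesTotal")
  TRUE
})

#' Lung-field segmentation parameters
#'
#' Threshold-and-morphology recipe: binarize below \code{airThreshold},
#' discard components touching the image border (outside air), keep the
#' \code{keepComponents} largest remaining components (the two lungs),
#' close with a disk of \code{closingRadius} pixels and optionally fill
#' interior holes (vessels, nodules).
#'
#' @slot airThreshold HU threshold separating aerated lung from soft tissue.
#' @slot keepComponents number of components to keep.
#' @slot closingRadius morphological closing radius, pixels.
#' @slot fillHoles fill enclosed holes.
#' @export
setClass("SegParams",
         representation(airThreshold = "numeric", keepComponents = "integer",
                        closingRadius = "integer", fillHoles = "logical"),
         prototype(airThreshold = -320, keepComponents = 2L,
                   closingRadius = 5L, fillHoles = TRUE))

setValidity("SegParams", function(object) {
  if (object@airThreshold >= 0) return("airThreshold must be negative (HU)")
  if (object@keepComponents < 1L) return("keepComponents must be >= 1")
  if (object@closingRadius < 0L) return("closingRadius must be >= 0")
  TRUE
})

#' @param airThreshold,keepComponents,closingRadius,fillHoles see slots.
#' @rdname SegParams-class
#' @export
segParams <- function(airThreshold = -320, keepComponents = 2,
                      closingRadius = 5, fillHoles = TRUE) {
  new("SegParams", airThreshold = as.numeric(airThreshold),
      keepComponents = as.integer(keepComponents),
      closingRadius = as.integer(closingRadius), fillHoles = as.logical(fillHoles))
}

#' Repeated patient-wise split experiment parameters
#'
#' @slot nRepeats number of repeated split/tune/test rounds.
#' @slot tuningFraction fraction of patients used for cut-off tuning.
#' @slot seed base seed; each repeat derives its own stream from
#'   \code{(seed, repeat index)}.
#' @slot splitUnit always \code{"patient"}: all slices of a patient fall on
#'   the same side of the split.
#' @export
setClass("ExperimentParams",
         representation(nRepeats = "integer", tuningFraction = "numeric",
                        seed = "integer", splitUnit = "character"),
         prototype(nRepeats = 5L, tuningFraction = 2 / 3, seed = 0L,
                   splitUnit = "patient"))

setValidity("ExperimentParams", function(object) {
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  if (object@tuningFraction <= 0 || object@tuningFraction >= 1)
    return("tuningFraction must lie in (0, 1)")
  if (object@splitUnit != "patient") return("only patient-wise splits are supported")
  TRUE
})

#' @param nRepeats,tuningFraction,seed see slots.
#' @rdname ExperimentParams-class
#' @export
experimentParams <- function(nRepeats = 5, tuningFraction = 2 / 3, seed = 0) {
  new("ExperimentParams", nRepeats = as.integer(nRepeats),
      tuningFraction = as.numeric(tuningFraction), seed = as.integer(seed),
      splitUnit = "patient")
}

#' Synthetic chest-phantom specification
#'
#' One axial chest-like slice: a soft-tissue body ellipse over background
#' air, two aerated-lung ellipses with Gaussian HU noise, small
#' vessel disks, and optionally a fibrotic subpleural honeycomb band or a
#' solid nodule. The honeycomb is a jittered hexagonal lattice of low-HU
#' lumina separated by walls whose HU is drawn per wall segment from
#' Normal(wallMeanHu + overlapDelta, wallSdHu); inside the -700..-400 HU
#' sweep only a subset of wall segments is foreground at any threshold, so
#' the lesion fragments into many components (high b0).
#'
#' @slot imageSize edge length in pixels.
#' @slot spacing isotropic pixel spacing in mm.
#' @slot bodyHu,lungHu,vesselHu tissue attenuations (HU).
#' @slot noiseSd lung parenchyma noise SD (HU).
#' @slot nVessels number of vessel disks.
#' @slot vesselRadiusMm range (min, max) of vessel radii in mm.
#' @slot lesion \code{"none"}, \code{"fibrosis"} or \code{"nodule"}.
#' @slot fibrosis list: \code{bandWidthMm}, \code{cellDiameterMm},
#'   \code{wallThicknessMm}, \code{wallMeanHu}, \code{wallSdHu}, \code{lumenHu}.
#' @slot nodule list: \code{radiusMm}, \code{hu}.
#' @slot overlapDelta HU shift added to the wall mean; more negative values
#'   push walls toward aerated-lung attenuation and shrink the class
#'   separation.
#' @slot seed integer; fully determines the output raster.
#' @export
setClass("PhantomSpec",
         representation(imageSize = "integer", spacing = "numeric",
                        bodyHu = "numeric", lungHu = "numeric",
                        noiseSd = "numeric", nVessels = "integer",
                        vesselHu = "numeric", vesselRadiusMm = "numeric",
                        lesion = "character", fibrosis = "list",
                        nodule = "list", overlapDelta = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  huPars <- c(object@bodyHu, object@lungHu, object@vesselHu,
              object@fibrosis$wallMeanHu, object@fibrosis$lumenHu,
              object@nodule$hu)
  if (any(abs(huPars) > 1024)) return("HU parameters must lie in [-1024, 1024]")
  if (object@imageSize < 64L) return("imageSize must be >= 64")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (!object@lesion %in% c("none", "fibrosis", "nodule"))
    return("lesion must be none, fibrosis or nodule")
  TRUE
})

#' @param imageSize,spacing,bodyHu,lungHu,noiseSd,nVessels,vesselHu see slots.
#' @param vesselRadiusMm vessel radius range (mm).
#' @param lesion lesion type.
#' @param fibrosis,nodule lesion parameter lists; supplied entries override
#'   the defaults.
#' @param overlapDelta HU shift of the wall mean.
#' @param seed integer seed.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(imageSize = 256, spacing = 0.7, bodyHu = 40,
                        lungHu = -850, noiseSd = 30, nVessels = 15,
                        vesselHu = 0, vesselRadiusMm = c(1, 2),
                        lesion = c("none", "fibrosis", "nodule"),
                        fibrosis = list(), nodule = list(),
                        overlapDelta = 0, seed = 0) {
  fib <- utils::modifyList(
    list(bandWidthMm = 15, cellDiameterMm = 4, wallThicknessMm = 1,
         wallMeanHu = -550, wallSdHu = 100, lumenHu = -820), fibrosis)
  nod <- utils::modifyList(list(radiusMm = 12, hu = 20), nodule)
  new("PhantomSpec", imageSize = as.integer(imageSize),
      spacing = as.numeric(spacing), bodyHu = as.numeric(bodyHu),
      lungHu = as.numeric(lungHu), noiseSd = as.numeric(noiseSd),
      nVessels = as.integer(nVessels), vesselHu = as.numeric(vesselHu),
      vesselRadiusMm = as.numeric(vesselRadiusMm), lesion = match.arg(lesion),
      fibrosis = fib, nodule = nod, overlapDelta = as.numeric(overlapDelta),
      seed = as.integer(seed))
}

#' Synthetic cohort specification
#'
#' A cohort of phantom "patients" per class, with \code{slicesPerPatient}
#' slices each. Class names map to lesion types: \code{fibrosis} carries a
#' honeycomb band, \code{lung_cancer} a nodule, \code{non_fibrosis} no
#' lesion. Per-slice seeds are derived deterministically from
#' \code{baseSeed}.
#'
#' @slot nPatients named integer vector, e.g.
#'   \code{c(fibrosis = 10, non_fibrosis = 10)}.
#' @slot slicesPerPatient slices per patient.
#' @slot template shared \linkS4class{PhantomSpec}; its lesion and seed
#'   fields are overridden per class/slice.
#' @slot baseSeed integer.
#' @export
setClass("CohortSpec",
         representation(nPatients = "integer", slicesPerPatient = "integer",
                        template = "PhantomSpec", baseSeed = "integer"))

setValidity("CohortSpec", function(object) {
  ok <- c("fibrosis", "non_fibrosis", "lung_cancer")
  if (is.null(names(object@nPatients)) || !all(names(object@nPatients) %in% ok))
    return("nPatients must be named with classes fibrosis/non_fibrosis/lung_cancer")
  if (any(object@nPatients < 1L)) return("each class needs >= 1 patient")
  if (object@slicesPerPatient < 1L) return("slicesPerPatient must be >= 1")
  TRUE
})

#' @param nPatients named patient counts per class.
#' @param slicesPerPatient slices per patient.
#' @param template shared \linkS4class{PhantomSpec}.
#' @param baseSeed integer.
#' @rdname CohortSpec-class
#' @export
cohortSpec <- function(nPatients = c(fibrosis = 10, non_fibrosis = 10),
                       slicesPerPatient = 2, template = phantomSpec(),
                       baseSeed = 0) {
  np <- as.integer(nPatients)
  names(np) <- names(nPatients)
  new("CohortSpec", nPatients = np,
      slicesPerPatient = as.integer(slicesPerPatient), template = template,
      baseSeed = as.integer(baseSeed))
}
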