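## Readers and writers. NIfTI carries HU and spacing natively; PNG is
## 8-bit and therefore paired with a JSON sidecar recording the linear HU
## calibration and the pixel spacing; DICOM reading is a minimal
## single-frame, uncompressed, explicit-VR little-endian parser (no R DICOM
## reader is part of the supported stack).

sidecarPath <- function(path) sub("(\\.nii\\.gz|\\.[^.]+)$", ".json", path)

#' Read a CT slice
#'
#' Dispatches on the file extension: \code{.nii/.nii.gz} via RNifti
#' (spacing from pixdim), \code{.png} via the png package plus a JSON
#' sidecar with the HU calibration (\code{huMin}, \code{huMax},
#' \code{spacing}), \code{.dcm} via the built-in DICOM parser (HU from
#' rescale slope/intercept). A PNG without sidecar yields 8-bit intensities
#' 0..255 and spacing (1, 1) with a warning.
#'
#' @param path input file.
#' @param patientId,sliceId,label metadata attached to the slice.
#' @return a \linkS4class{CTSlice}.
#' @export
readCT <- function(path, patientId = NA_character_, sliceId = NA_character_,
                   label = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    m <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
    sp <- RNifti::pixdim(img)[1:2]
  } else if (grepl("\\.png$", low)) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    sc <- sidecarPath(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      m <- raw * (meta$huMax - meta$huMin) + meta$huMin
      sp <- as.numeric(meta$spacing)
    } else {
      warning("PNG without sidecar: spacing set to (1, 1) mm, values are raw 8-bit intensities")
      m <- round(raw * 255)
      sp <- c(1, 1)
    }
  } else if (grepl("\\.dcm$", low)) {
    d <- readDicomSlice(path)
    m <- d$hu
    sp <- d$spacing
  } else stop("unsupported CT format: ", path)
  ctSlice(m, spacing = sp, patientId = patientId, sliceId = sliceId,
          label = label)
}

#' Write a CT slice
#'
#' NIfTI stores HU as float64 (bitwise round trip); PNG stores an 8-bit
#' linear rescaling and writes the calibration sidecar.
#'
#' @param slice a \linkS4class{CTSlice}.
#' @param path output file (\code{.nii}, \code{.nii.gz} or \code{.png}).
#' @return the path, invisibly.
#' @export
writeCT <- function(slice, path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(slice@hu)
    RNifti::pixdim(img) <- slice@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.png$", low)) {
    lo <- min(slice@hu); hi <- max(slice@hu)
    if (hi == lo) hi <- lo + 1
    png::writePNG((slice@hu - lo) / (hi - lo), path)
    jsonlite::write_json(list(huMin = lo, huMax = hi, spacing = slice@spacing,
                              patientId = slice@patientId,
                              sliceId = slice@sliceId, label = slice@label),
                         sidecarPath(path), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported CT format: ", path)
  invisible(path)
}

#' Read / write a binary mask (NIfTI 0/1 or PNG 0/255)
#'
#' @param path mask file.
#' @return \code{readMask}: logical matrix.
#' @export
readMask <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    matrix(as.numeric(img) > 0.5, dim(img)[1], dim(img)[2])
  } else if (grepl("\\.png$", low)) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    raw > 0.5
  } else stop("unsupported mask format: ", path)
}

#' @rdname readMask
#' @param mask logical matrix.
#' @param spacing pixel spacing in mm (recorded for NIfTI).
#' @export
writeMask <- function(mask, path, spacing = c(1, 1)) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(mask * 1)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.png$", low)) {
    png::writePNG(mask * 1, path)
  } else stop("unsupported mask format: ", path)
  invisible(path)
}

#' Write an HF map with its JSON sidecar
#'
#' NIfTI stores the map as float64. PNG export is an 8-bit linear rescale
#' for visualization only; the scale factor is recorded in the sidecar.
#' The sidecar also records the map parameters, spacing, skip counts and
#' the slice feature.
#'
#' @param map an \linkS4class{HFMap}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHFMap <- function(map, path) {
  low <- tolower(path)
  meta <- list(params = mapParamsToList(map@params), spacing = map@spacing,
               sliceId = map@sliceId, tilesTotal = map@tilesTotal,
               tilesSkipped = map@tilesSkipped,
               sliceFeature = sliceFeature(map),
               coordinateConvention = "row-major, origin top-left, half-open tile footprints")
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(map@values)
    RNifti::pixdim(img) <- map@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.png$", low)) {
    hi <- max(map@values, 1e-12)
    png::writePNG(map@values / hi, path)
    meta$pngScaleFactor <- hi
  } else stop("unsupported HF map format: ", path)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- parameter (de)serialization ------------------------------------------

mapParamsToList <- function(p) {
  list(tileSize = p@tileSize, shift = p@shift, skipFraction = p@skipFraction,
       standardization = p@standardization, index = p@index, mode = p@mode,
       profile = list(thresholdLo = p@profile@thresholdLo,
                      thresholdHi = p@profile@thresholdHi,
                      thresholdStep = p@profile@thresholdStep,
                      polarity = p@profile@polarity,
                      connectivity = list(
                        foreground = p@profile@connectivity@foreground,
                        background = p@profile@connectivity@background)))
}

mapParamsFromList <- function(x) {
  pr <- x$profile
  mapParams(tileSize = x$tileSize, shift = x$shift,
            skipFraction = x$skipFraction, standardization = x$standardization,
            index = x$index, mode = x$mode,
            profile = profileParams(pr$thresholdLo, pr$thresholdHi,
                                    pr$thresholdStep, pr$polarity,
                                    connectivityRule(pr$connectivity$foreground,
                                                     pr$connectivity$background)))
}

#' Run configuration
#'
#' Bundles the map, segmentation and experiment parameters with paths and a
#' log level; round-trips losslessly through a JSON config file.
#'
#' @param map a \linkS4class{MapParams}.
#' @param seg a \linkS4class{SegParams}.
#' @param experiment an \linkS4class{ExperimentParams}.
#' @param paths named list of input/output paths.
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return list of class \code{"runConfig"}.
#' @export
runConfig <- function(map = mapParams(), seg = segParams(),
                      experiment = experimentParams(), paths = list(),
                      logLevel = "info") {
  structure(list(map = map, seg = seg, experiment = experiment, paths = paths,
                 logLevel = logLevel), class = "runConfig")
}

#' @rdname runConfig
#' @param config a \code{"runConfig"}.
#' @param path JSON file.
#' @export
writeRunConfig <- function(config, path) {
  x <- list(map = mapParamsToList(config$map),
            seg = list(airThreshold = config$seg@airThreshold,
                       keepComponents = config$seg@keepComponents,
                       closingRadius = config$seg@closingRadius,
                       fillHoles = config$seg@fillHoles),
            experiment = list(nRepeats = config$experiment@nRepeats,
                              tuningFraction = config$experiment@tuningFraction,
                              seed = config$experiment@seed),
            paths = config$paths, logLevel = config$logLevel)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  runConfig(map = mapParamsFromList(x$map),
            seg = segParams(x$seg$airThreshold, x$seg$keepComponents,
                            x$seg$closingRadius, x$seg$fillHoles),
            experiment = experimentParams(x$experiment$nRepeats,
                                          x$experiment$tuningFraction,
                                          x$experiment$seed),
            paths = as.list(x$paths), logLevel = x$logLevel)
}

## ---- minimal DICOM --------------------------------------------------------

readU16 <- function(con) readBin(con, "integer", 1, size = 2, signed = FALSE,
                                 endian = "little")
readU32 <- function(con) readBin(con, "integer", 1, size = 4, endian = "little")

#' Read a single-frame DICOM CT slice
#'
#' Minimal parser for uncompressed, explicit-VR little-endian single-frame
#' files: extracts Rows, Columns, PixelSpacing, BitsAllocated,
#' PixelRepresentation, RescaleSlope/Intercept and PixelData, and returns
#' HU = slope x stored + intercept. Other transfer syntaxes are rejected.
#'
#' @param path a \code{.dcm} file.
#' @return list with \code{hu} (matrix) and \code{spacing} (mm).
#' @export
readDicomSlice <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128)
  if (!identical(rawToChar(readBin(con, "raw", 4)), "DICM"))
    stop("not a DICOM file (missing DICM magic): ", path)
  long32 <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  repeat {
    grp <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = "little")
    if (length(grp) == 0) break
    elm <- readU16(con)
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% long32) {
      readBin(con, "raw", 2)
      len <- readU32(con)
    } else {
      len <- readU16(con)
    }
    key <- sprintf("%04x,%04x", grp, elm)
    payload <- readBin(con, "raw", len)
    tags[[key]] <- list(vr = vr, bytes = payload)
    if (key == "7fe0,0010") break
  }
  need <- function(key, name) {
    if (is.null(tags[[key]]))
      stop("DICOM tag (", key, ") ", name, " missing in ", path)
    tags[[key]]
  }
  asU16 <- function(x) readBin(x$bytes, "integer", 1, size = 2, signed = FALSE,
                               endian = "little")
  asDS <- function(x) as.numeric(strsplit(trimws(rawToChar(x$bytes)),
                                          "\\\\")[[1]])
  ts <- tags[["0002,0010"]]
  if (!is.null(ts)) {
    syntax <- trimws(rawToChar(ts$bytes[ts$bytes != as.raw(0)]))
    if (syntax != "1.2.840.10008.1.2.1")
      stop("unsupported DICOM transfer syntax ", syntax,
           " (only explicit VR little endian is supported)")
  }
  rows <- asU16(need("0028,0010", "Rows"))
  cols <- asU16(need("0028,0011", "Columns"))
  bits <- asU16(need("0028,0100", "BitsAllocated"))
  if (bits != 16) stop("only 16-bit DICOM pixel data is supported")
  signed <- asU16(need("0028,0103", "PixelRepresentation")) == 1
  slope <- asDS(need("0028,1053", "RescaleSlope"))
  intercept <- asDS(need("0028,1052", "RescaleIntercept"))
  spacing <- asDS(need("0028,0030", "PixelSpacing"))
  pix <- need("7fe0,0010", "PixelData")
  stored <- readBin(pix$bytes, "integer", rows * cols, size = 2,
                    signed = signed, endian = "little")
  ## DICOM pixel order is row by row (left-to-right, top-to-bottom)
  m <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE)
  list(hu = slope * m + intercept, spacing = spacing)
}
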