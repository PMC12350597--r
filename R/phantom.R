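## Synthetic chest phantom: body and lung ellipses, parenchymal noise,
## vessel disks, and either a subpleural honeycomb band (fibrosis) or a
## solid nodule (lung cancer). Everything is drawn from the PhantomSpec
## seed, so identical specifications give identical rasters.

ellipseMask <- function(n, centerRow, centerCol, semiRow, semiCol) {
  r <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - centerRow) / semiRow)^2 + ((cc - centerCol) / semiCol)^2 <= 1
}

phantomGeometry <- function(n) {
  list(body = c(row = n / 2, col = n / 2, a = 0.36 * n, b = 0.46 * n),
       lungLeft = c(row = 0.52 * n, col = n / 2 - 0.225 * n,
                    a = 0.26 * n, b = 0.15 * n),
       lungRight = c(row = 0.52 * n, col = n / 2 + 0.225 * n,
                     a = 0.26 * n, b = 0.15 * n))
}

drawDisk <- function(hu, r0, c0, radius, value) {
  n <- nrow(hu)
  rs <- max(1L, floor(r0 - radius)):min(n, ceiling(r0 + radius))
  cs <- max(1L, floor(c0 - radius)):min(ncol(hu), ceiling(c0 + radius))
  sub <- outer((rs - r0)^2, (cs - c0)^2, "+") <= radius^2
  hu[rs, cs][sub] <- value
  hu
}

## Jittered hexagonal lattice of cell centers covering a bounding box.
hexCenters <- function(rowRange, colRange, pitch, jitterFrac = 0.18) {
  rowPitch <- pitch * sqrt(3) / 2
  rows <- seq(rowRange[1] - pitch, rowRange[2] + pitch, by = rowPitch)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    offset <- if (i %% 2 == 0) pitch / 2 else 0
    cols <- seq(colRange[1] - pitch + offset, colRange[2] + pitch, by = pitch)
    out[[i]] <- cbind(rows[i], cols)
  }
  centers <- do.call(rbind, out)
  centers + matrix(stats::runif(length(centers), -jitterFrac * pitch,
                                jitterFrac * pitch), nrow(centers), 2)
}

## Nearest and second-nearest center for each pixel (chunked distance
## matrices keep memory modest).
nearestTwo <- function(px, centers, chunk = 2048L) {
  p <- nrow(px)
  i1 <- integer(p); i2 <- integer(p)
  d1 <- numeric(p); d2 <- numeric(p)
  cr <- centers[, 1]; cc <- centers[, 2]
  for (start in seq(1L, p, by = chunk)) {
    sel <- start:min(p, start + chunk - 1L)
    D <- outer(px[sel, 1], cr, "-")^2 + outer(px[sel, 2], cc, "-")^2
    j1 <- max.col(-D, ties.method = "first")
    ind <- cbind(seq_along(sel), j1)
    e1 <- D[ind]
    D[ind] <- Inf
    j2 <- max.col(-D, ties.method = "first")
    i1[sel] <- j1; i2[sel] <- j2
    d1[sel] <- sqrt(e1); d2[sel] <- sqrt(D[cbind(seq_along(sel), j2)])
  }
  list(i1 = i1, i2 = i2, d1 = d1, d2 = d2)
}

#' Generate one synthetic chest slice
#'
#' Draws the phantom described by a \linkS4class{PhantomSpec}: a soft-tissue
#' body ellipse over -1000 HU air, two aerated-lung ellipses with Gaussian
#' noise, random vessel disks, and optionally a fibrotic subpleural
#' honeycomb band or a solid nodule. The returned ground-truth mask is the
#' exact union of the two analytic lung ellipses. HU are clipped to
#' [-1024, 1024].
#'
#' The honeycomb mechanism: within the subpleural band, pixels are assigned
#' to jittered hexagonal cells; pixels near a boundary between two cells
#' form a wall segment whose HU is drawn once per segment from
#' Normal(wallMeanHu + overlapDelta, wallSdHu). At any single threshold of
#' the -700..-400 HU sweep only a subset of segments is foreground, so the
#' lesion fragments into many small components -- the high-b0 signature the
#' feature is built on.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{slice} (a \linkS4class{CTSlice}),
#'   \code{mask} (ground-truth logical lung mask) and \code{label}.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@imageSize
  sp <- spec@spacing
  geo <- phantomGeometry(n)
  body <- ellipseMask(n, geo$body["row"], geo$body["col"], geo$body["a"],
                      geo$body["b"])
  lungL <- ellipseMask(n, geo$lungLeft["row"], geo$lungLeft["col"],
                       geo$lungLeft["a"], geo$lungLeft["b"])
  lungR <- ellipseMask(n, geo$lungRight["row"], geo$lungRight["col"],
                       geo$lungRight["a"], geo$lungRight["b"])
  lung <- lungL | lungR

  label <- switch(spec@lesion, none = "non_fibrosis", fibrosis = "fibrosis",
                  nodule = "lung_cancer")

  hu <- withSeed(spec@seed, {
    hu <- matrix(-1000, n, n)
    hu[body] <- spec@bodyHu
    hu[lung] <- spec@lungHu + stats::rnorm(sum(lung), 0, spec@noiseSd)

    ## depth inside the lung field, pixels (for vessel placement + band)
    depth <- matrix(as.numeric(EBImage::distmap(lung * 1)), n, n)

    for (k in seq_len(spec@nVessels)) {
      rad <- stats::runif(1, spec@vesselRadiusMm[1], spec@vesselRadiusMm[2]) / sp
      cand <- which(lung & depth > rad + 1)
      ctr <- cand[sample.int(length(cand), 1)]
      hu <- drawDisk(hu, (ctr - 1) %% n + 1, (ctr - 1) %/% n + 1, rad,
                     spec@vesselHu)
    }

    if (spec@lesion == "fibrosis") {
      f <- spec@fibrosis
      bandPx <- f$bandWidthMm / sp
      if (bandPx >= min(geo$lungLeft["a"], geo$lungLeft["b"]))
        stop("fibrosis band does not fit inside the lung")
      band <- lung & depth <= bandPx
      idx <- which(band)
      px <- cbind((idx - 1) %% n + 1, (idx - 1) %/% n + 1)
      pitch <- f$cellDiameterMm / sp
      centers <- hexCenters(range(px[, 1]), range(px[, 2]), pitch)
      nn <- nearestTwo(px, centers)
      isWall <- (nn$d2 - nn$d1) <= f$wallThicknessMm / sp
      segId <- pmin(nn$i1, nn$i2) * (nrow(centers) + 1) +
        pmax(nn$i1, nn$i2)
      seg <- factor(segId[isWall])
      segHu <- stats::rnorm(nlevels(seg), f$wallMeanHu + spec@overlapDelta,
                            f$wallSdHu)
      hu[idx[!isWall]] <- f$lumenHu
      hu[idx[isWall]] <- segHu[as.integer(seg)]
    } else if (spec@lesion == "nodule") {
      nod <- spec@nodule
      radPx <- nod$radiusMm / sp
      ctr <- geo$lungRight
      if (radPx + 2 >= min(ctr["a"], ctr["b"]))
        stop("nodule does not fit inside the lung")
      hu <- drawDisk(hu, ctr["row"], ctr["col"], radPx, nod$hu)
    }
    pmin(pmax(hu, -1024), 1024)
  })

  list(slice = ctSlice(hu, spacing = c(sp, sp), label = label), mask = lung,
       label = label)
}

#' Generate a synthetic cohort
#'
#' Generates \code{nPatients} phantom patients per class with
#' \code{slicesPerPatient} slices each; per-slice seeds are derived
#' deterministically from \code{baseSeed}, so two cohorts from the same
#' spec are identical. When \code{dir} is given, slices and ground-truth
#' masks are written as NIfTI and the manifest as CSV (existing target
#' files are an error).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param dir optional output directory.
#' @return list with \code{manifest} (data.frame: patientId, sliceId,
#'   label, and file paths when written), \code{slices} (list of
#'   \linkS4class{CTSlice}) and \code{masks} (list of logical matrices).
#' @export
generateCohort <- function(spec, dir = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  lesionFor <- c(fibrosis = "fibrosis", non_fibrosis = "none",
                 lung_cancer = "nodule")
  prefixFor <- c(fibrosis = "F", non_fibrosis = "N", lung_cancer = "C")
  slices <- list(); masks <- list(); rows <- list()
  idx <- 0L
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (class in names(spec@nPatients)) {
    for (p in seq_len(spec@nPatients[[class]])) {
      pid <- sprintf("%s%02d", prefixFor[[class]], p)
      for (s in seq_len(spec@slicesPerPatient)) {
        idx <- idx + 1L
        sid <- sprintf("%s_s%d", pid, s)
        pspec <- initialize(spec@template, lesion = lesionFor[[class]],
                            seed = deriveSeed(spec@baseSeed, idx))
        ph <- generatePhantom(pspec)
        sl <- initialize(ph$slice, patientId = pid, sliceId = sid)
        slices[[idx]] <- sl
        masks[[idx]] <- ph$mask
        row <- data.frame(patientId = pid, sliceId = sid, label = ph$label,
                          stringsAsFactors = FALSE)
        if (!is.null(dir)) {
          slicePath <- file.path(dir, paste0(sid, ".nii.gz"))
          maskPath <- file.path(dir, paste0(sid, "_mask.nii.gz"))
          if (file.exists(slicePath) || file.exists(maskPath))
            stop("output path collision: ", slicePath)
          writeCT(sl, slicePath)
          writeMask(ph$mask, maskPath, spacing = spacing(sl))
          row$slicePath <- slicePath
          row$maskPath <- maskPath
        }
        rows[[idx]] <- row
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, slices = slices, masks = masks)
}
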