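## Slice-wise classification: patient-wise tuning/testing splits, ROC
## analysis of the slice feature, Youden-index cut-off, confusion metrics,
## and the repeated experiment.

checkRecords <- function(records) {
  need <- c("patientId", "sliceId", "feature", "label")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (any(!is.finite(records$feature))) stop("features must be finite")
  records
}

#' Patient-wise tuning/testing split
#'
#' Splits on unique patient ids so all slices of a patient land on the same
#' side. The tuning side receives \code{round(tuningFraction x n_patients)}
#' patients. A split leaving either side without both classes is resampled
#' (with a message). Reproducible from \code{(seed, repeatIndex)}.
#'
#' @param records data.frame with \code{patientId}, \code{sliceId},
#'   \code{feature}, \code{label}.
#' @param params an \linkS4class{ExperimentParams}.
#' @param repeatIndex 1-based repeat number.
#' @return list with data.frames \code{tuning} and \code{testing}.
#' @export
patientSplit <- function(records, params = experimentParams(), repeatIndex = 1L) {
  records <- checkRecords(records)
  pat <- unique(records[, c("patientId", "label")])
  if (anyDuplicated(pat$patientId))
    stop("a patient carries more than one label")
  nPat <- nrow(pat)
  nTune <- round(params@tuningFraction * nPat)
  if (nTune < 1 || nTune >= nPat) stop("tuning fraction leaves an empty side")
  classes <- unique(pat$label)
  withSeed(deriveSeed(params@seed, repeatIndex), {
    for (attempt in 1:100) {
      tunePat <- sample(pat$patientId, nTune)
      tuneCls <- pat$label[pat$patientId %in% tunePat]
      testCls <- pat$label[!pat$patientId %in% tunePat]
      if (all(classes %in% tuneCls) && all(classes %in% testCls)) break
      if (attempt == 100) stop("could not find a split with both classes on both sides")
      message("resampling split ", repeatIndex, ": a class was absent from one side")
    }
    list(tuning = records[records$patientId %in% tunePat, , drop = FALSE],
         testing = records[!records$patientId %in% tunePat, , drop = FALSE])
  })
}

#' ROC curve of a slice feature
#'
#' Decision rule: predict positive when feature >= cutpoint. Candidate
#' cutpoints are the midpoints between consecutive distinct sorted feature
#' values, with -Inf and +Inf sentinels; AUROC is the trapezoidal area of
#' the (FPR, TPR) curve.
#'
#' @param feature numeric vector.
#' @param positive logical vector (TRUE = positive class), same length.
#' @return list of class \code{"rocResult"}: \code{cutpoints}, \code{tpr},
#'   \code{fpr}, \code{auroc}.
#' @export
rocCurve <- function(feature, positive) {
  stopifnot(length(feature) == length(positive), is.logical(positive))
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present for ROC analysis")
  v <- sort(unique(feature))
  cutpoints <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  tp <- vapply(cutpoints, function(ct) sum(feature >= ct & positive),
               integer(1))
  fp <- vapply(cutpoints, function(ct) sum(feature >= ct & !positive),
               integer(1))
  tpr <- tp / nPos
  fpr <- fp / nNeg
  o <- order(fpr, tpr)  # fpr ascending for the trapezoid
  auroc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  structure(list(cutpoints = cutpoints, tpr = tpr, fpr = fpr,
                 tp = tp, fp = fp, nPos = nPos, nNeg = nNeg, auroc = auroc),
            class = "rocResult")
}

#' Youden-index cut-off
#'
#' Maximizes J = TPR - FPR = sensitivity + specificity - 1 over the ROC
#' cutpoints; ties are broken toward the lowest cutpoint (favouring
#' sensitivity at equal J).
#'
#' @param roc a \code{"rocResult"} from \code{\link{rocCurve}}.
#' @return list of class \code{"cutoffResult"}: \code{cutoff},
#'   \code{youdenJ}.
#' @export
youdenCutoff <- function(roc) {
  # exact integer score: J * nPos * nNeg = TP * nNeg - FP * nPos, so the
  # lowest-cutpoint tie rule is immune to floating-point jitter
  score <- roc$tp * roc$nNeg - roc$fp * roc$nPos
  o <- order(roc$cutpoints)
  best <- o[which.max(score[o])]
  structure(list(cutoff = roc$cutpoints[best],
                 youdenJ = roc$tpr[best] - roc$fpr[best]),
            class = "cutoffResult")
}

#' Classification performance metrics
#'
#' accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP). A zero denominator yields \code{NA}, never a
#' silent 0 (e.g. precision with no positive prediction).
#'
#' @param predicted,actual logical vectors (TRUE = positive), same length.
#' @return named list \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{precision}.
#' @export
confusionMetrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            is.logical(predicted), is.logical(actual))
  tp <- sum(predicted & actual); fn <- sum(!predicted & actual)
  tn <- sum(!predicted & !actual); fp <- sum(predicted & !actual)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = rate(tp + tn, length(actual)),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       precision = rate(tp, tp + fp))
}

#' Repeated patient-wise split experiment
#'
#' For each repeat: patient-wise split, ROC on the tuning slices, Youden
#' cut-off, then confusion metrics of "feature >= cutoff => positive" on the
#' testing slices. Reports per-repeat rows and the mean and SD of the
#' cut-off, tuning AUROC and the four metrics (SD is 0 by convention for a
#' single repeat, flagged by \code{singleRepeat}).
#'
#' @param records feature records (see \code{\link{patientSplit}}).
#' @param params an \linkS4class{ExperimentParams}.
#' @param positive label treated as the positive class.
#' @return list of class \code{"experimentResult"}: \code{perRepeat}
#'   (data.frame), \code{summary} (data.frame of mean/sd), \code{positive},
#'   \code{singleRepeat}.
#' @export
repeatedExperiment <- function(records, params = experimentParams(),
                               positive = "fibrosis") {
  records <- checkRecords(records)
  if (!positive %in% records$label)
    stop("positive class '", positive, "' absent from records")
  if (length(unique(records$label)) != 2)
    stop("records must contain exactly two classes")
  rows <- vector("list", params@nRepeats)
  for (r in seq_len(params@nRepeats)) {
    split <- tryCatch(patientSplit(records, params, r),
                      error = function(e) stop("repeat ", r, ": ",
                                               conditionMessage(e)))
    tunePos <- split$tuning$label == positive
    roc <- rocCurve(split$tuning$feature, tunePos)
    cut <- youdenCutoff(roc)
    testPos <- split$testing$label == positive
    m <- confusionMetrics(split$testing$feature >= cut$cutoff, testPos)
    rows[[r]] <- data.frame(repeatIndex = r, cutoff = cut$cutoff,
                            youdenJ = cut$youdenJ, aurocTuning = roc$auroc,
                            accuracy = m$accuracy, sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            precision = m$precision)
  }
  per <- do.call(rbind, rows)
  quant <- c("cutoff", "aurocTuning", "accuracy", "sensitivity",
             "specificity", "precision")
  sdOr0 <- function(x) if (length(x) < 2) 0 else stats::sd(x, na.rm = TRUE)
  summary <- data.frame(
    quantity = quant,
    mean = vapply(per[quant], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per[quant], sdOr0, numeric(1)),
    row.names = NULL)
  structure(list(perRepeat = per, summary = summary, positive = positive,
                 singleRepeat = params@nRepeats == 1L),
            class = "experimentResult")
}

#' @export
print.experimentResult <- function(x, ...) {
  cat(sprintf("Repeated slice-wise experiment (positive = %s, %d repeats%s)\n",
              x$positive, nrow(x$perRepeat),
              if (x$singleRepeat) "; SD = 0 by convention" else ""))
  print(x$summary, digits = 4)
  invisible(x)
}
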