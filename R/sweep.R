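## Parameter sweep over HF-map settings: one repeated experiment per
## configuration, reporting the mean tuning AUROC and the runtime.

#' Sweep HF-map parameters over a cohort
#'
#' For every row of \code{grid}, builds \linkS4class{MapParams} from
#' \code{base} with the row's overrides, computes the cohort's slice
#' features, runs the repeated patient-wise experiment and records the mean
#' tuning AUROC and runtime. Infeasible configurations (e.g. shift larger
#' than the tile) are marked invalid and the sweep continues. Deterministic
#' given the experiment seed.
#'
#' @param cohort a cohort list (see \code{\link{generateCohort}}).
#' @param grid data.frame with any of the columns \code{tileSize},
#'   \code{shift}, \code{thresholdStep}, \code{standardization},
#'   \code{index}, \code{mode}.
#' @param base baseline \linkS4class{MapParams}.
#' @param experiment an \linkS4class{ExperimentParams}.
#' @param seg a \linkS4class{SegParams}, or \code{NULL} for ground-truth
#'   masks.
#' @param positive positive class label.
#' @return \code{grid} with added columns \code{valid}, \code{meanAuroc},
#'   \code{runtimeSec}.
#' @examples
#' \donttest{
#' co <- generateCohort(cohortSpec(nPatients = c(fibrosis = 2, non_fibrosis = 2)))
#' parameterSweep(co, expand.grid(index = c("b0", "b1"),
#'                                stringsAsFactors = FALSE),
#'                seg = NULL)
#' }
#' @export
parameterSweep <- function(cohort, grid, base = mapParams(),
                           experiment = experimentParams(), seg = segParams(),
                           positive = "fibrosis") {
  known <- c("tileSize", "shift", "thresholdStep", "standardization",
             "index", "mode")
  extra <- setdiff(names(grid), known)
  if (length(extra)) stop("unknown sweep columns: ", paste(extra, collapse = ", "))
  grid$valid <- NA
  grid$meanAuroc <- NA_real_
  grid$runtimeSec <- NA_real_
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    res <- tryCatch({
      prof <- base@profile
      if (!is.null(row$thresholdStep))
        prof <- initialize(prof, thresholdStep = as.numeric(row$thresholdStep))
      p <- initialize(base, profile = prof)
      for (f in intersect(names(row), c("tileSize", "shift")))
        slot(p, f) <- as.integer(row[[f]])
      for (f in intersect(names(row), c("standardization", "index", "mode")))
        slot(p, f) <- as.character(row[[f]])
      validObject(p)
      t0 <- proc.time()[["elapsed"]]
      feats <- cohortFeatures(cohort, p, seg)
      ex <- repeatedExperiment(feats, experiment, positive)
      list(auroc = ex$summary$mean[ex$summary$quantity == "aurocTuning"],
           dt = proc.time()[["elapsed"]] - t0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      grid$valid[i] <- FALSE
    } else {
      grid$valid[i] <- TRUE
      grid$meanAuroc[i] <- res$auroc
      grid$runtimeSec[i] <- res$dt
    }
  }
  grid
}
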