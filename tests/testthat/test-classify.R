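mannWhitneyAuroc <- function(feature, positive) {
  pos <- feature[positive]; neg <- feature[!positive]
  pairs <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(pairs)
}

bruteForceYouden <- function(feature, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  v <- sort(unique(feature))
  cuts <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  best <- -Inf; bestCut <- NA; bestJ <- NA
  for (ct in sort(cuts)) {
    tp <- sum(feature >= ct & positive)
    fp <- sum(feature >= ct & !positive)
    score <- tp * nNeg - fp * nPos  # exact integer J comparison
    if (score > best) {
      best <- score; bestCut <- ct
      bestJ <- tp / nPos - fp / nNeg
    }
  }
  list(cutoff = bestCut, youdenJ = bestJ)
}

test_that("ROC analysis matches hand-computable cases", {
  r <- rocCurve(c(1, 2, 3, 5, 6, 7), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auroc, 1)
  r <- rocCurve(rep(2, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(r$auroc, 0.5)
  r <- rocCurve(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auroc, 0.75)  # 3 of 4 pairs ordered + 0 ties
  expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("TPR and FPR are monotone along the cutpoints", {
  set.seed(41)
  for (i in 1:20) {
    f <- round(rnorm(30), 1)
    lab <- runif(30) < 0.5
    if (!any(lab) || all(lab)) next
    r <- rocCurve(f, lab)
    o <- order(r$cutpoints)
    expect_true(all(diff(r$tpr[o]) <= 0))
    expect_true(all(diff(r$fpr[o]) <= 0))
  }
})

test_that("AUROC equals the Mann-Whitney pair count and survives monotone maps", {
  set.seed(42)
  for (i in 1:40) {
    f <- rnorm(25)
    if (i %% 2) f <- round(f, 1)  # alternate with and without ties
    lab <- runif(25) < 0.4
    if (!any(lab) || all(lab)) next
    r <- rocCurve(f, lab)
    expect_equal(r$auroc, mannWhitneyAuroc(f, lab))
    expect_equal(rocCurve(exp(f), lab)$auroc, r$auroc)
  }
})

test_that("the Youden cut-off matches brute-force J maximization", {
  r <- rocCurve(c(1, 2, 3, 5, 6, 7), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  cut <- youdenCutoff(r)
  expect_equal(cut$cutoff, 4)
  expect_equal(cut$youdenJ, 1)
  r <- rocCurve(rep(c(1, 2), 4), rep(c(TRUE, FALSE), 4))
  expect_equal(youdenCutoff(r)$youdenJ, 0)
  set.seed(43)
  for (i in 1:60) {
    f <- round(rnorm(20, sd = 2), 1)
    lab <- c(rep(TRUE, 8), rep(FALSE, 12))[order(runif(20))]
    cut <- youdenCutoff(rocCurve(f, lab))
    ref <- bruteForceYouden(f, lab)
    expect_equal(cut$cutoff, ref$cutoff)
    expect_equal(cut$youdenJ, ref$youdenJ)
  }
})

test_that("AUROC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (i in 1:10) {
    f <- rnorm(40) + rep(c(0, 1), each = 20)
    lab <- rep(c(FALSE, TRUE), each = 20)
    ours <- rocCurve(f, lab)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, f, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref)
  }
})

test_that("confusion metrics follow the standard formulas", {
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 6), rep(TRUE, 4))
  act <- c(rep(TRUE, 10), rep(FALSE, 10))
  m <- confusionMetrics(pred, act)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$precision, 8 / 12)
  perfect <- confusionMetrics(act, act)
  expect_true(all(unlist(perfect) == 1))
  m <- confusionMetrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(m$precision))
  expect_equal(m$specificity, 1)
})

test_that("patient-wise splits are reproducible and leak-free", {
  mkRecords <- function(nPos, nNeg, slices = 3) {
    pid <- c(sprintf("P%02d", seq_len(nPos)), sprintf("N%02d", seq_len(nNeg)))
    lab <- rep(c("fibrosis", "non_fibrosis"), c(nPos, nNeg))
    data.frame(patientId = rep(pid, each = slices),
               sliceId = paste0(rep(pid, each = slices), "_", seq_len(slices)),
               feature = runif(length(pid) * slices),
               label = rep(lab, each = slices))
  }
  set.seed(45)
  rec <- mkRecords(10, 8)  # 18 patients
  sp <- patientSplit(rec, experimentParams(seed = 7), repeatIndex = 2)
  expect_identical(length(unique(sp$tuning$patientId)), 12L)
  expect_identical(length(unique(sp$testing$patientId)), 6L)
  sp2 <- patientSplit(rec, experimentParams(seed = 7), repeatIndex = 2)
  expect_identical(sp, sp2)
  expect_false(identical(sp, patientSplit(rec, experimentParams(seed = 7), 3)))
  for (i in 1:100) {
    rec <- mkRecords(sample(3:8, 1), sample(3:8, 1), sample(1:4, 1))
    s <- patientSplit(rec, experimentParams(seed = i), repeatIndex = i %% 5)
    expect_length(intersect(s$tuning$sliceId, s$testing$sliceId), 0)
    expect_length(intersect(s$tuning$patientId, s$testing$patientId), 0)
    expect_identical(sort(c(s$tuning$sliceId, s$testing$sliceId)),
                     sort(rec$sliceId))
  }
})

test_that("the repeated experiment is deterministic and flags single repeats", {
  set.seed(46)
  rec <- data.frame(
    patientId = rep(sprintf("p%d", 1:8), each = 2),
    sliceId = sprintf("s%d", 1:16),
    feature = c(rnorm(8, 5), rnorm(8, 0)),
    label = rep(c("fibrosis", "non_fibrosis"), each = 8))
  e1 <- repeatedExperiment(rec, experimentParams(seed = 3))
  e2 <- repeatedExperiment(rec, experimentParams(seed = 3))
  expect_identical(e1, e2)
  single <- repeatedExperiment(rec, experimentParams(nRepeats = 1, seed = 3))
  expect_true(single$singleRepeat)
  expect_true(all(single$summary$sd == 0))
  expect_error(repeatedExperiment(rec, positive = "lung_cancer"), "absent")
})
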