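test_that("phantom generation is fully determined by its seed", {
  a <- generatePhantom(phantomSpec(lesion = "fibrosis", seed = 9))
  b <- generatePhantom(phantomSpec(lesion = "fibrosis", seed = 9))
  expect_identical(hu(a$slice), hu(b$slice))
  expect_identical(a$mask, b$mask)
  c <- generatePhantom(phantomSpec(lesion = "fibrosis", seed = 10))
  expect_false(identical(hu(a$slice), hu(c$slice)))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generatePhantom(phantomSpec(seed = 11, imageSize = 128)))
  expect_identical(runif(1), before)
})

test_that("the ground-truth mask is the analytic union of the lung ellipses", {
  n <- 128
  ph <- generatePhantom(phantomSpec(seed = 12, imageSize = n))
  r <- matrix(seq_len(n), n, n); cc <- t(r)
  inEllipse <- function(cr, ccol, a, b)
    ((r - cr) / a)^2 + ((cc - ccol) / b)^2 <= 1
  expected <- inEllipse(0.52 * n, n / 2 - 0.225 * n, 0.26 * n, 0.15 * n) |
    inEllipse(0.52 * n, n / 2 + 0.225 * n, 0.26 * n, 0.15 * n)
  expect_identical(ph$mask, expected)
})

test_that("cohorts have the advertised composition and are reproducible", {
  spec <- cohortSpec(nPatients = c(fibrosis = 3, non_fibrosis = 3),
                     slicesPerPatient = 2,
                     template = phantomSpec(imageSize = 128,
                                            fibrosis = list(bandWidthMm = 8)),
                     baseSeed = 4)
  co <- generateCohort(spec)
  expect_identical(nrow(co$manifest), 12L)
  expect_identical(length(unique(co$manifest$patientId)), 6L)
  expect_identical(sort(unique(co$manifest$label)),
                   c("fibrosis", "non_fibrosis"))
  co2 <- generateCohort(spec)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$slices[[5]]@hu, co2$slices[[5]]@hu)
})

test_that("a fibrotic lesion raises the slice feature above the normal lung", {
  pN <- generatePhantom(phantomSpec(lesion = "none", seed = 0))
  pF <- generatePhantom(phantomSpec(lesion = "fibrosis", seed = 0))
  fN <- sliceFeature(computeHFMap(pN$slice, pN$mask))
  fF <- sliceFeature(computeHFMap(pF$slice, pF$mask))
  expect_gt(fF, fN)
})

test_that("a lesion whose HU never enters the sweep leaves profiles unchanged", {
  # walls at -900 and lumina at -820 are below the -700 HU sweep floor, so
  # under the foreground = HU >= t polarity the lesion is invisible
  degF <- phantomSpec(lesion = "fibrosis", nVessels = 0, seed = 13,
                      fibrosis = list(wallMeanHu = -900, wallSdHu = 0))
  degN <- phantomSpec(lesion = "none", nVessels = 0, seed = 13)
  pF <- generatePhantom(degF); pN <- generatePhantom(degN)
  prF <- homologyProfile(hu(pF$slice), pF$mask)
  prN <- homologyProfile(hu(pN$slice), pN$mask)
  expect_identical(as.data.frame(prF), as.data.frame(prN))
  # walls pinned above the sweep ceiling are foreground at every threshold:
  # one constant wall network per lung, a constant +2 offset of b0
  degHi <- phantomSpec(lesion = "fibrosis", nVessels = 0, seed = 13,
                       fibrosis = list(wallMeanHu = -300, wallSdHu = 0))
  pH <- generatePhantom(degHi)
  prH <- homologyProfile(hu(pH$slice), pH$mask)
  diffB0 <- bettiCurve(prH, "b0") - bettiCurve(prN, "b0")
  expect_true(all(diffB0 == diffB0[1]))
  expect_gt(diffB0[1], 0)
})

test_that("class mean features are ordered fibrosis > nodule > normal", {
  co <- generateCohort(cohortSpec(
    nPatients = c(fibrosis = 10, non_fibrosis = 10, lung_cancer = 10),
    baseSeed = 0))
  feats <- cohortFeatures(co, seg = NULL)  # ground-truth masks
  m <- tapply(feats$feature, feats$label, mean)
  expect_gt(m[["fibrosis"]], m[["lung_cancer"]])
  expect_gt(m[["lung_cancer"]], m[["non_fibrosis"]])
})

test_that("lesions that cannot fit inside the lung are rejected", {
  expect_error(generatePhantom(phantomSpec(lesion = "nodule", imageSize = 128,
                                           nodule = list(radiusMm = 30))),
               "fit")
  expect_error(generatePhantom(phantomSpec(lesion = "fibrosis", imageSize = 64,
                                           fibrosis = list(bandWidthMm = 30))),
               "fit")
})
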