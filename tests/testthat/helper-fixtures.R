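# Small binary rasters used across the topology tests.

annulus5 <- function() {
  m <- matrix(FALSE, 5, 5)
  m[2:4, 2:4] <- TRUE
  m[3, 3] <- FALSE
  m
}

doubleAnnulus <- function() {
  # two side-by-side annuli sharing no pixels: b0 = 2, b1 = 2
  m <- matrix(FALSE, 5, 9)
  m[2:4, 2:4] <- TRUE; m[3, 3] <- FALSE
  m[2:4, 6:8] <- TRUE; m[3, 7] <- FALSE
  m
}

checkerboard4 <- function() {
  m <- matrix(FALSE, 4, 4)
  m[(row(m) + col(m)) %% 2 == 0] <- TRUE
  m
}

randomRaster <- function(nr = 16, nc = 16, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Cohorts and their slice features are expensive; cache them for the session.
.testCache <- new.env(parent = emptyenv())

cachedCohort <- function(delta = 0, baseSeed = 0) {
  key <- sprintf("cohort_%g_%d", delta, baseSeed)
  if (is.null(.testCache[[key]]))
    .testCache[[key]] <- generateCohort(
      cohortSpec(template = phantomSpec(overlapDelta = delta),
                 baseSeed = baseSeed))
  .testCache[[key]]
}

cachedFeatures <- function(delta = 0, baseSeed = 0) {
  key <- sprintf("feats_%g_%d", delta, baseSeed)
  if (is.null(.testCache[[key]]))
    .testCache[[key]] <- cohortFeatures(cachedCohort(delta, baseSeed))
  .testCache[[key]]
}
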