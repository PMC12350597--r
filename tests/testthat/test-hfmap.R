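stepParams <- function(tileSize, shift, standardization = "none") {
  mapParams(tileSize = tileSize, shift = shift,
            standardization = standardization,
            profile = profileParams(thresholdStep = 100))
}

test_that("tile origins enumerate the fully-inside sliding positions", {
  expect_identical(nrow(iterTiles(c(512, 512), 32, 8)), 3721L)
  o <- iterTiles(c(32, 32), 32, 8)
  expect_identical(o, cbind(row = 1L, col = 1L))
  o <- iterTiles(c(16, 16), 4, 4)
  expect_identical(nrow(o), 16L)  # non-overlapping tiling
  expect_true(all(o + 4 - 1 <= 16))
  # row-major: row varies slowest
  expect_true(all(diff(o[, "row"]) >= 0))
  expect_error(iterTiles(c(16, 16), 32, 8), "exceeds")
})

test_that("the skip rule is strict at its boundary", {
  tm <- matrix(FALSE, 20, 20)
  expect_true(tileSkip(tm, 0.95))            # fraction outside = 1
  expect_false(tileSkip(!tm, 0.95))          # fraction outside = 0
  tm[seq_len(20)] <- TRUE                    # 20/400 inside: outside = 0.95
  expect_false(tileSkip(tm, 0.95))           # exactly at the bound: keep
  tm[20] <- FALSE                            # 381/400 outside
  expect_true(tileSkip(tm, 0.95))
})

test_that("standardization modes divide by the advertised quantity", {
  expect_equal(standardizeSummary(10, "pixel_area", c(0.5, 0.5)), 40)
  expect_equal(standardizeSummary(10, "pixel_spacing", c(0.5, 0.5)), 20)
  expect_equal(standardizeSummary(12, "tile_pixels", tileValidPixels = 1024),
               0.01171875)
  expect_equal(standardizeSummary(10, "none", c(0.5, 0.5)), 10)
  expect_error(standardizeSummary(10, "tile_pixels", tileValidPixels = 0),
               "positive")
})

test_that("overlap accumulation reproduces the analytic uniform-slice map", {
  sl <- ctSlice(matrix(-500, 16, 16))
  m <- computeHFMap(sl, params = stepParams(4, 2))
  v <- mapValues(m)
  expect_identical(v[1, 1], 1)               # corner: single covering tile
  expect_identical(v[8, 8], 4)               # interior: four covering tiles
  expect_identical(sliceFeature(m), 4)
  # shift = tile: single coverage everywhere
  m1 <- computeHFMap(sl, params = stepParams(4, 4))
  expect_true(all(mapValues(m1) == 1))
})

test_that("an empty mask yields an all-zero map with a warning", {
  sl <- ctSlice(matrix(-500, 16, 16))
  expect_warning(m <- computeHFMap(sl, matrix(FALSE, 16, 16),
                                   stepParams(4, 2)), "empty")
  expect_true(all(mapValues(m) == 0))
  expect_identical(sliceFeature(m), 0)
})

test_that("pixel-area standardization scales as the inverse squared spacing", {
  set.seed(31)
  huM <- matrix(runif(256, -900, -300), 16, 16)
  p <- mapParams(tileSize = 4, shift = 2,
                 profile = profileParams(thresholdStep = 50))
  m1 <- computeHFMap(ctSlice(huM, spacing = c(0.5, 0.5)), params = p)
  m2 <- computeHFMap(ctSlice(huM, spacing = c(1.0, 1.0)), params = p)
  expect_equal(mapValues(m1), 4 * mapValues(m2))
})

test_that("maps are deterministic and bounded by tile coverage", {
  set.seed(32)
  huM <- matrix(runif(1024, -900, -300), 32, 32)
  mask <- matrix(runif(1024) < 0.9, 32, 32)
  p <- mapParams(tileSize = 8, shift = 4, standardization = "none",
                 profile = profileParams(thresholdStep = 25))
  m1 <- computeHFMap(ctSlice(huM), mask, p)
  m2 <- computeHFMap(ctSlice(huM), mask, p)
  expect_identical(mapValues(m1), mapValues(m2))
  coverage <- (p@tileSize / p@shift)^2
  perTile <- max(vapply(seq_len(nrow(iterTiles(c(32, 32), 8, 4))), function(i) {
    o <- iterTiles(c(32, 32), 8, 4)[i, ]
    pr <- homologyProfile(huM[o[1]:(o[1] + 7), o[2]:(o[2] + 7)],
                          mask[o[1]:(o[1] + 7), o[2]:(o[2] + 7)], p@profile)
    if (length(thresholds(pr)) == 0) 0 else summarizeProfile(pr)
  }, numeric(1)))
  expect_true(max(mapValues(m1)) <= coverage * perTile)
})

test_that("relaxing the skip rule can only preserve or increase the map", {
  set.seed(33)
  huM <- matrix(runif(576, -900, -300), 24, 24)
  mask <- matrix(FALSE, 24, 24); mask[9:16, 9:16] <- TRUE
  base <- mapParams(tileSize = 8, shift = 4, standardization = "none",
                    profile = profileParams(thresholdStep = 50),
                    skipFraction = 0.5)
  lax <- initialize(base, skipFraction = 1)  # keeps every tile
  expect_true(all(mapValues(computeHFMap(ctSlice(huM), mask, lax)) >=
                    mapValues(computeHFMap(ctSlice(huM), mask, base))))
})
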