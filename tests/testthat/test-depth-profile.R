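mkProfile <- function(depth, y) depthProfile(depth, y)

test_that("normalization to the first point", {
  p <- mkProfile(c(0, 1, 2), c(2, 1, 0.5))
  expect_equal(intensities(normalizeToFirst(p)), c(1, 0.5, 0.25))
  const <- mkProfile(c(0, 1, 2), c(3, 3, 3))
  expect_equal(intensities(normalizeToFirst(const)), c(1, 1, 1))
  # idempotence
  n <- normalizeToFirst(p)
  expect_identical(normalizeToFirst(n), n)
  expect_error(normalizeToFirst(mkProfile(c(0, 1), c(0, 1))), "degenerate")
})

test_that("flat-region statistics use the sample sd", {
  p <- mkProfile(1:3, c(1, 1, 1))
  fs <- flatRegionStats(p, c(1, 3))
  expect_equal(fs$mean, 1)
  expect_equal(fs$sd, 0)
  p2 <- mkProfile(1:3, c(0.99, 1.00, 1.01))
  fs2 <- flatRegionStats(p2, c(1, 3))
  expect_equal(fs2$mean, 1)
  expect_equal(fs2$sd, 0.01)
  expect_error(flatRegionStats(p, c(1, 1.5)), "insufficient")
})

stepProfile <- function() {
  d <- depths(insertionScanSchedule())
  y <- ifelse(d < 4.4, 1, ifelse(d < 5, 1 - (d - 4.4) / 0.6 * 0.4, 0.6))
  mkProfile(d, y)
}

test_that("deviation onset finds a persistent exceedance", {
  p <- stepProfile()
  expect_equal(deviationOnset(p, 1, 0.005, k = 2, after = 3.5, boundaryMm = 5),
               4.5)  # first depth where the decline exceeds 2 sd
  # a clean constructed step at 4.4
  d <- depths(p)
  y <- ifelse(d < 4.4, 1, 0.5)
  expect_equal(deviationOnset(mkProfile(d, y), 1, 0.005, k = 2,
                              after = 3.5, boundaryMm = 5), 4.4)
  # constant profile never leaves the band
  expect_error(deviationOnset(mkProfile(d, rep(1, length(d))), 1, 0.005,
                              after = 3.5, boundaryMm = 5), "no onset")
})

test_that("persistence guard ignores an isolated spike", {
  d <- seq(0, 6, by = 0.2)
  y <- rep(1, length(d))
  y[d == 3] <- 0.8                    # isolated non-persistent dip
  y[d >= 4.4] <- 0.5                  # sustained decline from 4.4
  on <- deviationOnset(mkProfile(d, y), 1, 0.005, k = 2, after = 0,
                       boundaryMm = 6)
  expect_equal(on, 4.4)
})

test_that("detection depth is boundary minus onset", {
  res <- detectionDepth(stepProfile(), boundaryMm = 5)
  expect_s4_class(res, "DetectionDepthResult")
  expect_equal(res@boundaryDepth, 5)
  expect_equal(detectionDepthValue(res),
               res@boundaryDepth - onsetDepth(res))
  # the constructed ramp deviates detectably from 4.5 (flat sd = 0)
  expect_equal(detectionDepthValue(res), 0.5)
  # a hard step at 4.4 gives exactly 0.6
  d <- depths(stepProfile())
  y <- ifelse(d < 4.4, 1, 0.5)
  expect_equal(detectionDepthValue(detectionDepth(mkProfile(d, y), 5)), 0.6)
  # degenerate: onset at the boundary itself
  y2 <- ifelse(d < 5, 1, 0.5)
  expect_equal(detectionDepthValue(detectionDepth(mkProfile(d, y2), 5)), 0)
  expect_error(detectionDepth(stepProfile(), boundaryMm = 4.95), "depths")
})

test_that("detection depth is invariant under uniform rescaling", {
  d <- depths(stepProfile())
  y <- intensities(stepProfile())
  for (c in c(0.01, 7, 1e5)) {
    res <- detectionDepth(mkProfile(d, c * y), 5)
    expect_equal(detectionDepthValue(res), 0.5)
  }
})

test_that("increasing k never decreases the onset depth", {
  set.seed(5)
  d <- depths(insertionScanSchedule())
  y <- ifelse(d < 4.4, 1, ifelse(d < 5, 1 - (d - 4.4) / 0.6 * 0.4, 0.6)) +
    rnorm(length(d), 0, 0.004)
  y[1] <- 1
  p <- mkProfile(d, y)
  fs <- flatRegionStats(p, c(0, 3.5))
  onsets <- sapply(c(0.5, 1, 2, 3, 4), function(k)
    tryCatch(deviationOnset(p, fs$mean, fs$sd, k = k, after = 3.5,
                            boundaryMm = 5),
             error = function(e) Inf))
  expect_true(all(diff(onsets) >= 0))
})

test_that("estimator recovers a constructed onset under modest noise", {
  # noise sd below (step amplitude)/(2k) leaves the onset recoverable
  d <- seq(0, 6, by = 0.1)
  set.seed(99)
  onsets <- replicate(25, {
    y <- ifelse(d < 4.2, 1, 0.7) + rnorm(length(d), 0, 0.02)
    y[1] <- 1
    p <- mkProfile(d, pmax(y, 0))
    fs <- flatRegionStats(p, c(0, 3.5))
    tryCatch(deviationOnset(p, fs$mean, fs$sd, k = 2, after = 3.5,
                            boundaryMm = 6),
             error = function(e) NA_real_)
  })
  expect_true(all(!is.na(onsets)))
  # never off by more than one grid step, exact in the large majority
  expect_true(all(abs(onsets - 4.2) <= 0.1 + 1e-9))
  expect_gte(sum(onsets == 4.2), 20)
})
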