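test_that("dark/reference normalization is elementwise and guarded", {
  wl <- 340:1020
  sig <- nirSpectrum(wl, rep(600, 681))
  dark <- nirSpectrum(wl, rep(100, 681))
  ref <- nirSpectrum(wl, rep(1100, 681))
  expect_equal(intensities(normalizeReflectance(ref, dark, ref)),
               rep(1, 681))
  expect_equal(intensities(normalizeReflectance(dark, dark, ref)),
               rep(0, 681))
  mid <- nirSpectrum(wl, (intensities(dark) + intensities(ref)) / 2)
  expect_equal(intensities(normalizeReflectance(mid, dark, ref)),
               rep(0.5, 681))
  other <- nirSpectrum(wl + 1, rep(1, 681))
  expect_error(normalizeReflectance(sig, dark, other), "identical wavelength")
  badRef <- nirSpectrum(wl, rep(100, 681))
  expect_error(normalizeReflectance(sig, dark, badRef), "positive")
})

test_that("replicate averaging is the pointwise mean", {
  wl <- 340:1020
  s <- flatSpectrum(2)
  avg <- suppressWarnings(averageReplicates(list(s, flatSpectrum(0)), 20))
  expect_equal(intensities(avg), rep(1, 681))
  same <- replicate(20, flatSpectrum(3.5), simplify = FALSE)
  expect_equal(intensities(averageReplicates(same, 20)), rep(3.5, 681))
  expect_warning(averageReplicates(list(s, s), expectedCount = 20),
                 "expected 20")
  expect_error(averageReplicates(list()), "empty")
  # scalar-loop cross-check of the elementwise mean
  set.seed(3)
  reps <- lapply(1:5, function(i) nirSpectrum(wl, runif(681)))
  avg2 <- suppressWarnings(averageReplicates(reps, 5))
  manual <- sapply(seq_along(wl), function(j)
    mean(sapply(reps, function(s) intensities(s)[j])))
  expect_equal(intensities(avg2), manual)
})

test_that("area factor is the trapezoidal integral over the window", {
  expect_equal(areaFactor(flatSpectrum(1)), 680)
  expect_equal(areaFactor(flatSpectrum(0)), 0)
  ramp <- nirSpectrum(340:1020, seq(0, 1, length.out = 681))
  expect_equal(areaFactor(ramp), 340)
  # additivity over adjacent subintervals
  s <- nirSpectrum(340:1020, sin(seq(0, 3, length.out = 681)) + 2)
  expect_equal(areaFactor(s, 340, 700) + areaFactor(s, 700, 1020),
               areaFactor(s, 340, 1020))
  # linearity in intensity
  s5 <- nirSpectrum(340:1020, 5 * intensities(s))
  expect_equal(areaFactor(s5), 5 * areaFactor(s))
  short <- nirSpectrum(400:900, rep(1, 501))
  expect_error(areaFactor(short), "cover")
})

test_that("peak factor is the window maximum with first-wavelength ties", {
  s <- nirSpectrum(c(340, 600, 1020), c(1, 5, 3))
  expect_equal(as.numeric(peakFactor(s)), 5)
  expect_equal(as.numeric(peakFactor(flatSpectrum(4))), 4)
  tied <- nirSpectrum(c(340, 600, 700, 1020), c(1, 9, 9, 3))
  pk <- peakFactor(tied)
  expect_equal(as.numeric(pk), 9)
  expect_equal(attr(pk, "wavelengthNm"), 600)
})

test_that("slope factor equals the OLS slope times the reporting scale", {
  wl <- 340:1020
  line <- nirSpectrum(wl, 0.02 * wl + 3)
  expect_equal(slopeFactor(line), 0.02 * 1000)
  expect_equal(slopeFactor(flatSpectrum(7)), 0)
  # noisy line: agreement with an independent normal-equations solve
  set.seed(8)
  y <- 0.004 * wl + rnorm(681, 0, 0.3)
  s <- nirSpectrum(wl, y)
  idx <- wl >= 500 & wl <= 550
  X <- cbind(1, wl[idx])
  beta <- solve(t(X) %*% X, t(X) %*% y[idx])
  expect_equal(slopeFactor(s), beta[2] * 1000, tolerance = 1e-10)
  # window endpoints are inclusive
  tiny <- nirSpectrum(c(500, 550), c(0, 5))
  expect_equal(slopeFactor(tiny, scale = 1), 0.1)
  expect_error(slopeFactor(nirSpectrum(c(505, 560), c(1, 2)), 500, 550),
               "cover")
})

test_that("pattern factors compose the three spectral summaries with muSr", {
  pf <- extractPatternFactors(flatSpectrum(1), muSr = 17)
  expect_equal(areaValue(pf), 680)
  expect_equal(peakValue(pf), 1)
  expect_equal(slopeValue(pf), 0)
  expect_equal(muSr(pf), 17)
  expect_error(extractPatternFactors(nirSpectrum(500:600, rep(1, 101))),
               "cover")
})

test_that("factor tables carry depths, labels and factors per record", {
  ds <- generateDataset(generatorConfig(replicates = 2), seed = 4)
  tb <- factorTable(ds)
  expect_equal(names(tb), c("depth_mm", "region", "mu_s_reduced", "peak",
                            "area", "slope"))
  expect_equal(nrow(tb), 41)
  expect_equal(tb$depth_mm, depths(ds))
  expect_equal(tb$region, regionLabels(ds))
  expect_true(all(is.finite(tb$area)))
})
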