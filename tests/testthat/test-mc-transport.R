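test_that("free-path sampling follows the exponential law", {
  expect_equal(sampleStep(10, exp(-1)), 0.1)
  expect_equal(sampleStep(1, 1), 0)
  set.seed(11)
  u <- runif(1e5)
  s <- sampleStep(5, u)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 5), 3 * se)
  expect_error(sampleStep(0, 0.5), "positive")
  expect_error(sampleStep(-1, 0.5), "positive")
  expect_error(sampleStep(5, 0), "\\(0, 1\\]")
})

test_that("Henyey-Greenstein deflection has mean cosine g and unit directions", {
  set.seed(21)
  for (g in c(0, 0.5, 0.9)) {
    ct <- hgCosTheta(g, runif(1e5))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
    expect_true(all(ct >= -1 & ct <= 1))
  }
  # direction update preserves unit norm and realizes the sampled cosine
  set.seed(22)
  for (i in 1:50) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    u1 <- runif(1)
    u2 <- runif(1)
    out <- sampleScatter(0.9, u1, u2, v)
    expect_lt(abs(sum(out^2) - 1), 1e-9)
    expect_equal(sum(out * v), hgCosTheta(0.9, u1), tolerance = 1e-6)
  }
  expect_error(sampleScatter(1, 0.5, 0.5, c(0, 0, 1)), "g must be")
  expect_error(sampleScatter(0.9, 0.5, 0.5, c(0, 0, 2)), "unit 3-vector")
})

test_that("per-packet weight ledger accounts for the injected weight", {
  m <- boneTwoLayerModel()
  p <- probeGeometry()
  for (h in c(0, 2, 4.95)) {
    acc <- tracePhoton(m, p, h, seed = 7, nPhotons = 300)
    expect_lt(max(abs(rowSums(acc) - 1)), 1e-9)
    expect_true(all(acc$detected >= 0 & acc$escaped >= 0 & acc$absorbed >= 0))
  }
})

test_that("a practically opaque medium detects essentially nothing", {
  opaque <- layeredModel(list(opticalProperties(muA = 1e4, muSr = 17.23)), 7)
  acc <- tracePhoton(opaque, probeGeometry(), 2, seed = 3, nPhotons = 200)
  expect_lt(sum(acc$detected), 1e-3)
})

test_that("compiled tracer matches the scalar reference tracer on a shared stream", {
  m <- boneTwoLayerModel()
  # wide-acceptance probe so the 100 shared-stream packets include detections
  p <- probeGeometry(fiberDiameterUm = 600, separationUm = 600,
                     acceptanceCosMin = 0.1)
  impl <- tracePhoton(m, p, 4.8, seed = 12345, nPhotons = 100)
  ref <- oracleTrace(m, p, 4.8, seed = 12345, nPhotons = 100)
  expect_identical(impl$detected, unname(ref[, "detected"]))
  expect_identical(impl$escaped, unname(ref[, "escaped"]))
  expect_identical(impl$absorbed, unname(ref[, "absorbed"]))
  expect_identical(impl$roulette, unname(ref[, "roulette"]))
  expect_gt(sum(impl$detected > 0), 0)  # the comparison exercises detections
})

test_that("reflectance simulation is seed-reproducible and depth-valid", {
  m <- boneTwoLayerModel()
  p <- probeGeometry()
  r1 <- simulateReflectance(m, p, 2, nPhotons = 5000, seed = 99)
  r2 <- simulateReflectance(m, p, 2, nPhotons = 5000, seed = 99)
  expect_identical(as.numeric(r1), as.numeric(r2))
  r3 <- simulateReflectance(m, p, 2, nPhotons = 5000, seed = 100)
  expect_false(as.numeric(r1) == as.numeric(r3))
  expect_error(simulateReflectance(m, p, 8, 100, 1), "within the model")
  expect_error(simulateReflectance(m, p, 2, 0, 1), "nPhotons")
  expect_error(tracePhoton(m, p, 2, seed = -1), "seed")
})

test_that("refractive-index mismatch between layers is rejected, not ignored", {
  m <- layeredModel(list(opticalProperties(0.41, 17.23, n = 1.38),
                         opticalProperties(0.21, 12.02, n = 1.5)),
                    c(5, 2))
  expect_error(simulateReflectance(m, probeGeometry(), 2, 100, 1),
               "not implemented")
})

test_that("reflectance is translation-invariant in a homogeneous medium", {
  m <- smallHomogeneousModel(20)
  p <- probeGeometry()
  r1 <- simulateReflectance(m, p, 8, nPhotons = 3e4, seed = 31)
  r2 <- simulateReflectance(m, p, 12, nPhotons = 3e4, seed = 77)
  tol <- 3 * sqrt(attr(r1, "se")^2 + attr(r2, "se")^2)
  expect_lt(abs(as.numeric(r1) - as.numeric(r2)), tol)
})

test_that("higher reduced scattering returns more light at small separation", {
  p <- probeGeometry()
  spongy <- layeredModel(list(opticalProperties(0.41, 17.23)), 20)
  compact <- layeredModel(list(opticalProperties(0.21, 12.02)), 20)
  rs <- simulateReflectance(spongy, p, 10, nPhotons = 1.5e5, seed = 5)
  rc <- simulateReflectance(compact, p, 10, nPhotons = 1.5e5, seed = 6)
  expect_gt(as.numeric(rs) - 3 * attr(rs, "se"),
            as.numeric(rc) + 3 * attr(rc, "se"))
})

test_that("depth scan returns a valid profile with per-depth sub-seeds", {
  m <- smallHomogeneousModel(20)
  p <- probeGeometry()
  sch <- scanSchedule(c(8, 9, 10))
  prof <- depthScan(m, p, sch, nPhotons = 4000, seed = 17)
  expect_s4_class(prof, "DepthProfile")
  expect_false(isNormalized(prof))
  expect_equal(depths(prof), c(8, 9, 10))
  # each depth uses sub-seed seed + index - 1
  expect_identical(intensities(prof)[2],
                   as.numeric(simulateReflectance(m, p, 9, 4000, 18)))
  n <- normalizeToFirst(prof)
  expect_identical(intensities(n)[1], 1)
  expect_error(depthScan(m, p, scanSchedule(c(8, 25)), 100, 1), "within")
})

test_that("homogeneous-medium scan is flat within Monte Carlo noise", {
  m <- smallHomogeneousModel(20)
  p <- probeGeometry()
  prof <- depthScan(m, p, scanSchedule(seq(6, 14, by = 2)), nPhotons = 2e4,
                    seed = 41)
  n <- normalizeToFirst(prof)
  relse <- profileSE(prof) / intensities(prof)
  tol <- 3 * sqrt(relse^2 + relse[1]^2)
  expect_true(all(abs(intensities(n) - 1) < tol))
})
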