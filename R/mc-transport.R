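## Photon Monte Carlo transport for the dual-fiber probe in a layered slab.
## Internals work in cm (optical coefficients are per cm); the user-facing
## depth unit is mm.

# Russian-roulette defaults (MCML conventions): packets below `wmin` survive
# with probability `psurv`, survivors are reweighted by 1/psurv.
.ROULETTE_WMIN <- 1e-4
.ROULETTE_PSURV <- 0.1

.checkModelProbe <- function(model, probe) {
  stopifnot(is(model, "LayeredModel"), is(probe, "ProbeGeometry"))
  ns <- vapply(model@layers, function(p) p@n, numeric(1))
  if (length(unique(ns)) > 1L)
    stop("not implemented: refractive-index mismatch at internal boundaries ",
         "(all layers must share n; Fresnel optics are not modeled)")
  invisible(TRUE)
}

.checkSeed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 ||
      seed != floor(seed) || seed >= 2^31)
    stop("seed must be a non-negative integer below 2^31")
  invisible(as.numeric(seed))
}

.kernelArgs <- function(model, probe, probeDepthMm) {
  total <- totalThickness(model)
  if (length(probeDepthMm) != 1L || !is.finite(probeDepthMm) ||
      probeDepthMm < 0 || probeDepthMm > total)
    stop(sprintf("probe depth must lie within the model (0 to %g mm)", total))
  list(
    muA = vapply(model@layers, function(p) p@muA, numeric(1)),
    muS = vapply(model@layers, function(p) muS(p), numeric(1)),
    g = vapply(model@layers, function(p) p@g, numeric(1)),
    thicknessCm = model@thicknessMm / 10,
    probeDepthCm = probeDepthMm / 10,
    detOffsetCm = probe@separationUm * 1e-4,
    detRadiusCm = probe@fiberDiameterUm / 2 * 1e-4,
    cosMin = probe@acceptanceCosMin)
}

#' Sample an exponential free path
#'
#' Free path length between photon interactions, `-log(u) / muT`, for total
#' attenuation coefficient `muT = muA + muS`.
#'
#' @param muT total attenuation coefficient (1/cm), `> 0`.
#' @param u uniform random deviate(s) in `(0, 1]`.
#' @return Path length(s) in cm.
#' @examples
#' sampleStep(10, exp(-1))  # 0.1 cm
#' @export
sampleStep <- function(muT, u) {
  if (any(!is.finite(muT)) || any(muT <= 0))
    stop("muT must be positive and finite")
  if (any(!is.finite(u)) || any(u <= 0) || any(u > 1))
    stop("u must lie in (0, 1]")
  -log(u) / muT
}

#' Sample a Henyey-Greenstein scattering direction
#'
#' Deflects a unit direction vector by a polar angle whose cosine follows the
#' Henyey-Greenstein distribution with anisotropy `g` (isotropic for
#' `g = 0`), with azimuth uniform on `[0, 2*pi)`.
#'
#' @param g anisotropy in `[0, 1)`.
#' @param u1,u2 uniform random deviates in `(0, 1]`.
#' @param incoming unit 3-vector.
#' @return New unit 3-vector.
#' @examples
#' sampleScatter(0.9, 0.5, 0.25, c(0, 0, 1))
#' @export
sampleScatter <- function(g, u1, u2, incoming) {
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (length(incoming) != 3L || abs(sum(incoming^2) - 1) > 1e-8)
    stop("incoming must be a unit 3-vector")
  ct <- hgCosTheta(g, u1)
  st <- sqrt(1 - ct * ct)
  phi <- 2 * pi * u2
  cp <- cos(phi)
  sp <- sin(phi)
  ux <- incoming[1]; uy <- incoming[2]; uz <- incoming[3]
  if (abs(uz) > 0.99999) {
    out <- c(st * cp, st * sp, if (uz >= 0) ct else -ct)
  } else {
    den <- sqrt(1 - uz * uz)
    out <- c(st * (ux * uz * cp - uy * sp) / den + ux * ct,
             st * (uy * uz * cp + ux * sp) / den + uy * ct,
             -den * st * cp + uz * ct)
  }
  out
}

#' Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the polar deflection cosine; vectorized over `u`.
#'
#' @param g anisotropy in `[0, 1)`.
#' @param u uniform deviate(s) in `(0, 1]`.
#' @return Deflection cosine(s) in `[-1, 1]`; expectation equals `g`.
#' @export
hgCosTheta <- function(g, u) {
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (g == 0) {
    ct <- 2 * u - 1
  } else {
    tmp <- (1 - g * g) / (1 - g + 2 * g * u)
    ct <- (1 + g * g - tmp * tmp) / (2 * g)
  }
  pmin(1, pmax(-1, ct))
}

#' Trace photon packets with full weight accounting
#'
#' Launches `nPhotons` packets at the source-fiber position on the plane
#' `z = probeDepthMm`, initial direction into the tissue ahead of the probe,
#' and follows each until it is collected by the detector fiber, escapes
#' through an absorbing outer boundary, or is terminated by Russian roulette.
#' The per-packet ledger (detected + escaped + absorbed + roulette) accounts
#' for the injected unit weight to floating-point accuracy.
#'
#' @param model a [LayeredModel-class].
#' @param probe a [ProbeGeometry-class].
#' @param probeDepthMm probe tip depth H (mm from top surface).
#' @param seed non-negative integer seed for the internal rand48 stream.
#' @param nPhotons number of packets (default 1).
#' @return data.frame with one row per packet and columns `detected`,
#'   `escaped`, `absorbed`, `roulette` (net roulette weight adjustment).
#' @examples
#' m <- boneTwoLayerModel()
#' acc <- tracePhoton(m, probeGeometry(), probeDepthMm = 2, seed = 7,
#'                    nPhotons = 10)
#' rowSums(acc)  # all 1
#' @export
tracePhoton <- function(model, probe, probeDepthMm, seed, nPhotons = 1L) {
  .checkModelProbe(model, probe)
  seed <- .checkSeed(seed)
  if (nPhotons < 1) stop("nPhotons must be >= 1")
  a <- .kernelArgs(model, probe, probeDepthMm)
  res <- .mcTracePhotonsCpp(a$muA, a$muS, a$g, a$thicknessCm, a$probeDepthCm,
                            a$detOffsetCm, a$detRadiusCm, a$cosMin,
                            as.integer(nPhotons), seed,
                            .ROULETTE_WMIN, .ROULETTE_PSURV, TRUE)
  data.frame(detected = res$detected, escaped = res$escaped,
             absorbed = res$absorbed, roulette = res$roulette)
}

#' Simulate detected reflectance at one probe depth
#'
#' Mean detected packet weight per launched photon for the probe embedded at
#' depth `probeDepthMm`. Reproducible given `seed`.
#'
#' @inheritParams tracePhoton
#' @param nPhotons photons to launch (`>= 1`).
#' @return Detected reflectance (a single number) with attributes `se` (the
#'   Monte Carlo standard error) and `nPhotons`.
#' @examples
#' m <- boneTwoLayerModel()
#' simulateReflectance(m, probeGeometry(), 2, nPhotons = 2000, seed = 1)
#' @export
simulateReflectance <- function(model, probe, probeDepthMm, nPhotons, seed) {
  .checkModelProbe(model, probe)
  seed <- .checkSeed(seed)
  if (length(nPhotons) != 1L || !is.finite(nPhotons) || nPhotons < 1)
    stop("nPhotons must be >= 1")
  a <- .kernelArgs(model, probe, probeDepthMm)
  res <- .mcTracePhotonsCpp(a$muA, a$muS, a$g, a$thicknessCm, a$probeDepthCm,
                            a$detOffsetCm, a$detRadiusCm, a$cosMin,
                            as.integer(nPhotons), seed,
                            .ROULETTE_WMIN, .ROULETTE_PSURV, FALSE)
  n <- res$nPhotons
  m1 <- res$detectedSum / n
  v <- max(0, res$detectedSumSq / n - m1 * m1)
  structure(m1, se = sqrt(v / n), nPhotons = n)
}

#' Scan the probe through the slab
#'
#' Runs [simulateReflectance()] at every scheduled depth, with a distinct
#' deterministic sub-seed per depth (`seed + depth index - 1`), and returns
#' the raw reflectance profile. Use [normalizeToFirst()] for the profile
#' normalized to its first point.
#'
#' @inheritParams tracePhoton
#' @param schedule a [ScanSchedule-class] of probe depths (mm).
#' @param nPhotons photons per depth.
#' @return A raw [DepthProfile-class] with per-depth standard errors.
#' @export
depthScan <- function(model, probe, schedule, nPhotons, seed) {
  stopifnot(is(schedule, "ScanSchedule"))
  d <- depths(schedule)
  if (length(d) < 1L) stop("schedule must contain at least one depth")
  if (any(d > totalThickness(model)))
    stop("all schedule depths must lie within the model")
  seed <- .checkSeed(seed)
  refl <- numeric(length(d))
  se <- numeric(length(d))
  for (i in seq_along(d)) {
    r <- simulateReflectance(model, probe, d[i], nPhotons, seed + i - 1)
    refl[i] <- as.numeric(r)
    se[i] <- attr(r, "se")
  }
  depthProfile(d, refl, se = se, nPhotons = nPhotons, seed = seed,
               normalized = FALSE)
}
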