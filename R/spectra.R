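## Reflectance-spectrum handling: dark/reference normalization, replicate
## averaging, and the three spectral pattern factors (area, peak, slope).

.sameGrid <- function(a, b) {
  length(a@wavelength) == length(b@wavelength) &&
    all(a@wavelength == b@wavelength)
}

.windowIdx <- function(spectrum, lo, hi, minPoints = 2L, what = "window") {
  wl <- spectrum@wavelength
  if (lo >= hi) stop(sprintf("%s limits must satisfy lo < hi", what))
  if (min(wl) > lo || max(wl) < hi)
    stop(sprintf("spectrum does not cover the %s [%g, %g] nm", what, lo, hi))
  idx <- which(wl >= lo & wl <= hi)
  if (length(idx) < minPoints)
    stop(sprintf("insufficient data: fewer than %d grid points in the %s",
                 minPoints, what))
  idx
}

#' Dark/reference normalization of a measured spectrum
#'
#' Converts raw spectrometer counts to reflectance
#' `R = (signal - dark) / (reference - dark)`, elementwise on a shared
#' wavelength grid. The dark spectrum is recorded with the source off; the
#' reference on a ~99.9 percent reflectance standard.
#'
#' @param signal,dark,reference [Spectrum-class] objects on identical grids.
#' @return A [Spectrum-class] of normalized reflectance.
#' @export
normalizeReflectance <- function(signal, dark, reference) {
  stopifnot(is(signal, "Spectrum"), is(dark, "Spectrum"),
            is(reference, "Spectrum"))
  if (!.sameGrid(signal, dark) || !.sameGrid(signal, reference))
    stop("signal, dark and reference must share an identical wavelength grid")
  denom <- reference@intensity - dark@intensity
  if (any(denom <= 0))
    stop("reference - dark must be positive at every wavelength ",
         "(saturated or underflowed reference)")
  nirSpectrum(signal@wavelength, (signal@intensity - dark@intensity) / denom)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of a set of replicate spectra on a shared grid.
#' The measurement protocol records 20 replicates per probe position; a
#' deviating count is reported as a warning, not an error.
#'
#' @param spectra list of [Spectrum-class] objects on identical grids.
#' @param expectedCount expected number of replicates (default 20).
#' @return The averaged [Spectrum-class].
#' @export
averageReplicates <- function(spectra, expectedCount = 20L) {
  if (!length(spectra)) stop("insufficient data: empty replicate set")
  stopifnot(all(vapply(spectra, is, logical(1), class2 = "Spectrum")))
  for (s in spectra[-1])
    if (!.sameGrid(spectra[[1]], s))
      stop("all replicates must share an identical wavelength grid")
  if (length(spectra) != expectedCount)
    warning(sprintf("expected %d replicates, got %d",
                    expectedCount, length(spectra)))
  m <- vapply(spectra, function(s) s@intensity,
              numeric(length(spectra[[1]]@intensity)))
  nirSpectrum(spectra[[1]]@wavelength, rowMeans(as.matrix(m)))
}

#' Area pattern factor
#'
#' Trapezoidal integral of the intensity over the grid points inside
#' `[lo, hi]` (inclusive endpoints), by default the full 340-1020 nm
#' acquisition window.
#'
#' @param spectrum a [Spectrum-class].
#' @param lo,hi integration window (nm).
#' @return Integrated area (intensity x nm).
#' @examples
#' areaFactor(nirSpectrum(340:1020, rep(1, 681)))  # 680
#' @export
areaFactor <- function(spectrum, lo = 340, hi = 1020) {
  stopifnot(is(spectrum, "Spectrum"))
  idx <- .windowIdx(spectrum, lo, hi, minPoints = 2L, what = "area window")
  pracma::trapz(spectrum@wavelength[idx], spectrum@intensity[idx])
}

#' Peak pattern factor
#'
#' Maximum intensity within `[lo, hi]`; ties are broken by the smallest
#' wavelength, reported in the `wavelengthNm` attribute.
#'
#' @inheritParams areaFactor
#' @return The peak intensity, with attribute `wavelengthNm`.
#' @export
peakFactor <- function(spectrum, lo = 340, hi = 1020) {
  stopifnot(is(spectrum, "Spectrum"))
  idx <- .windowIdx(spectrum, lo, hi, minPoints = 1L, what = "peak window")
  v <- spectrum@intensity[idx]
  j <- which.max(v)  # first maximum = smallest wavelength on a sorted grid
  structure(v[j], wavelengthNm = spectrum@wavelength[idx][j])
}

#' Slope pattern factor
#'
#' Ordinary least-squares slope of intensity versus wavelength over the grid
#' points in `[lo, hi]` (inclusive; default 500-550 nm), multiplied by the
#' reporting scale. The scale (default 1000) is an arbitrary reporting
#' convention for count-scaled spectra and is configurable.
#'
#' @inheritParams areaFactor
#' @param scale reporting scale applied to the raw slope (default 1000).
#' @return Scaled slope (intensity per nm, times `scale`).
#' @export
slopeFactor <- function(spectrum, lo = 500, hi = 550, scale = 1000) {
  stopifnot(is(spectrum, "Spectrum"))
  idx <- .windowIdx(spectrum, lo, hi, minPoints = 2L, what = "slope window")
  x <- spectrum@wavelength[idx]
  y <- spectrum@intensity[idx]
  fit <- stats::lm.fit(cbind(1, x), y)
  unname(fit$coefficients[2]) * scale
}

#' Extract all pattern factors of a spectrum
#'
#' Bundles the area, peak and slope factors with the externally supplied
#' reduced scattering coefficient (whose estimation from spectra is outside
#' the scope of this package).
#'
#' @inheritParams areaFactor
#' @param muSr reduced scattering coefficient (1/cm) measured alongside the
#'   spectrum; `NA` when unavailable.
#' @param areaRange,slopeRange wavelength windows (nm).
#' @param slopeScale reporting scale for the slope.
#' @return A [PatternFactors-class] object.
#' @examples
#' pf <- extractPatternFactors(nirSpectrum(340:1020, rep(1, 681)), muSr = 17)
#' areaValue(pf); peakValue(pf); slopeValue(pf)
#' @export
extractPatternFactors <- function(spectrum, muSr = NA_real_,
                                  areaRange = c(340, 1020),
                                  slopeRange = c(500, 550),
                                  slopeScale = 1000) {
  pk <- peakFactor(spectrum, areaRange[1], areaRange[2])
  new("PatternFactors",
      area = areaFactor(spectrum, areaRange[1], areaRange[2]),
      peak = as.numeric(pk),
      peakWavelength = attr(pk, "wavelengthNm"),
      slope = slopeFactor(spectrum, slopeRange[1], slopeRange[2], slopeScale),
      muSr = as.numeric(muSr))
}

#' Assemble a labeled pattern-factor table
#'
#' Builds the per-depth factor table consumed by the threshold derivation:
#' one row per depth with the region label, reduced scattering coefficient
#' and the three spectral factors of the (averaged) spectrum.
#'
#' @param x a [LabeledDataset-class], or a list of [Spectrum-class] objects.
#' @param ... passed on to methods.
#' @return data.frame with columns `depth_mm`, `region`, `mu_s_reduced`,
#'   `peak`, `area`, `slope`.
#' @export
setGeneric("factorTable", function(x, ...) standardGeneric("factorTable"))

#' @describeIn factorTable factors of the replicate-averaged spectra of a
#'   synthetic dataset.
#' @param areaRange,slopeRange,slopeScale see [extractPatternFactors()].
#' @export
setMethod("factorTable", "LabeledDataset",
          function(x, areaRange = c(340, 1020), slopeRange = c(500, 550),
                   slopeScale = 1000) {
  sp <- lapply(seq_along(x@depthMm), function(i) averagedSpectrum(x, i))
  tb <- factorTable(sp, depthMm = x@depthMm, muSr = x@muSr,
                    region = x@region, areaRange = areaRange,
                    slopeRange = slopeRange, slopeScale = slopeScale)
  tb
})

#' @describeIn factorTable factors of a list of spectra with explicit depths,
#'   labels and scattering coefficients.
#' @param depthMm depths (mm), one per spectrum.
#' @param muSr reduced scattering coefficients, one per spectrum (or NA).
#' @param region region labels, one per spectrum (or NA).
#' @export
setMethod("factorTable", "list",
          function(x, depthMm, muSr = NA_real_, region = NA_character_,
                   areaRange = c(340, 1020), slopeRange = c(500, 550),
                   slopeScale = 1000) {
  stopifnot(length(depthMm) == length(x))
  muSr <- rep_len(as.numeric(muSr), length(x))
  region <- rep_len(as.character(region), length(x))
  rows <- lapply(seq_along(x), function(i) {
    pf <- extractPatternFactors(x[[i]], muSr = muSr[i], areaRange = areaRange,
                                slopeRange = slopeRange,
                                slopeScale = slopeScale)
    data.frame(depth_mm = depthMm[i], region = region[i],
               mu_s_reduced = pf@muSr, peak = pf@peak, area = pf@area,
               slope = pf@slope)
  })
  do.call(rbind, rows)
})
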