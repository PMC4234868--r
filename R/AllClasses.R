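#' @import methods
NULL

## ---------------------------------------------------------------------------
## Optical properties and layered slab geometry
## ---------------------------------------------------------------------------

#' Optical properties of one tissue layer
#'
#' Absorption, reduced scattering, scattering anisotropy and refractive index
#' of a homogeneous medium. The full scattering coefficient used by the photon
#' tracer is derived by the similarity relation `muS = muSr / (1 - g)`.
#'
#' @slot muA absorption coefficient (1/cm), `>= 0`.
#' @slot muSr reduced scattering coefficient (1/cm), `> 0`.
#' @slot g scattering anisotropy (mean cosine of the single-scattering
#'   deflection), in `[0, 1)`.
#' @slot n refractive index, `>= 1`.
#' @export
setClass("OpticalProperties",
         representation(muA = "numeric", muSr = "numeric",
                        g = "numeric", n = "numeric"))

setValidity("OpticalProperties", function(object) {
  msg <- character()
  for (s in c("muA", "muSr", "g", "n")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@muA < 0) msg <- c(msg, "muA must be >= 0")
  if (object@muSr <= 0) msg <- c(msg, "muSr must be > 0")
  if (object@g < 0 || object@g >= 1) msg <- c(msg, "g must be in [0, 1)")
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct optical properties
#'
#' @param muA absorption coefficient (1/cm).
#' @param muSr reduced scattering coefficient (1/cm).
#' @param g anisotropy factor (default 0.9, typical for soft tissue and bone).
#' @param n refractive index (default 1.38).
#' @return An [OpticalProperties-class] object.
#' @examples
#' spongy <- opticalProperties(muA = 0.41, muSr = 17.23)
#' muS(spongy)
#' @export
opticalProperties <- function(muA, muSr, g = 0.9, n = 1.38) {
  new("OpticalProperties", muA = as.numeric(muA), muSr = as.numeric(muSr),
      g = as.numeric(g), n = as.numeric(n))
}

#' @describeIn opticalProperties absorption coefficient accessor (1/cm).
#' @param object an `OpticalProperties` object.
#' @export
setGeneric("muA", function(object) standardGeneric("muA"))
#' @export
setMethod("muA", "OpticalProperties", function(object) object@muA)

#' @describeIn opticalProperties reduced scattering coefficient accessor (1/cm).
#' @export
setGeneric("muSr", function(object) standardGeneric("muSr"))
#' @export
setMethod("muSr", "OpticalProperties", function(object) object@muSr)

#' @describeIn opticalProperties anisotropy accessor.
#' @export
setGeneric("anisotropy", function(object) standardGeneric("anisotropy"))
#' @export
setMethod("anisotropy", "OpticalProperties", function(object) object@g)

#' @describeIn opticalProperties refractive index accessor.
#' @export
setGeneric("refIndex", function(object) standardGeneric("refIndex"))
#' @export
setMethod("refIndex", "OpticalProperties", function(object) object@n)

#' @describeIn opticalProperties full scattering coefficient
#'   `muSr / (1 - g)` (1/cm).
#' @export
setGeneric("muS", function(object) standardGeneric("muS"))
#' @export
setMethod("muS", "OpticalProperties", function(object) object@muSr / (1 - object@g))

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf(
    "OpticalProperties: muA = %g /cm, muSr = %g /cm (muS = %g /cm), g = %g, n = %g\n",
    object@muA, object@muSr, muS(object), object@g, object@n))
})

#' Layered slab model
#'
#' An ordered stack of homogeneous layers (top to bottom). Depth `z` increases
#' downward from the top surface; layer thicknesses are in millimetres.
#'
#' @slot layers list of [OpticalProperties-class], top layer first.
#' @slot thicknessMm numeric vector of layer thicknesses (mm), all `> 0`.
#' @export
setClass("LayeredModel",
         representation(layers = "list", thicknessMm = "numeric"))

setValidity("LayeredModel", function(object) {
  msg <- character()
  if (length(object@layers) < 1L) msg <- c(msg, "at least one layer required")
  if (!all(vapply(object@layers, is, logical(1), class2 = "OpticalProperties")))
    msg <- c(msg, "all layers must be OpticalProperties")
  if (length(object@thicknessMm) != length(object@layers))
    msg <- c(msg, "one thickness per layer required")
  if (any(!is.finite(object@thicknessMm)) || any(object@thicknessMm <= 0))
    msg <- c(msg, "all thicknesses must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Construct a layered slab model
#'
#' @param layers list of [OpticalProperties-class] objects, top layer first.
#' @param thicknessMm layer thicknesses in mm.
#' @return A [LayeredModel-class] object.
#' @examples
#' m <- layeredModel(
#'   list(opticalProperties(0.41, 17.23), opticalProperties(0.21, 12.02)),
#'   thicknessMm = c(5, 2))
#' totalThickness(m)
#' @export
layeredModel <- function(layers, thicknessMm) {
  if (is(layers, "OpticalProperties")) layers <- list(layers)
  new("LayeredModel", layers = layers, thicknessMm = as.numeric(thicknessMm))
}

#' The spongy-over-compact two-layer bone model
#'
#' Two-layer vertebra model at 690 nm: spongy bone
#' (muSr = 17.23 /cm, muA = 0.41 /cm, 5 mm) over compact bone
#' (muSr = 12.02 /cm, muA = 0.21 /cm, 2 mm), g = 0.9 and n = 1.38 in both.
#'
#' @return A [LayeredModel-class] object.
#' @export
boneTwoLayerModel <- function() {
  layeredModel(
    list(opticalProperties(muA = 0.41, muSr = 17.23),
         opticalProperties(muA = 0.21, muSr = 12.02)),
    thicknessMm = c(5, 2))
}

#' @describeIn layeredModel number of layers.
#' @param object a `LayeredModel`.
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))
#' @export
setMethod("nLayers", "LayeredModel", function(object) length(object@layers))

#' @describeIn layeredModel layer thicknesses (mm).
#' @export
setGeneric("layerThickness", function(object) standardGeneric("layerThickness"))
#' @export
setMethod("layerThickness", "LayeredModel", function(object) object@thicknessMm)

#' @describeIn layeredModel total slab thickness (mm).
#' @export
setGeneric("totalThickness", function(object) standardGeneric("totalThickness"))
#' @export
setMethod("totalThickness", "LayeredModel", function(object) sum(object@thicknessMm))

#' @describeIn layeredModel optical properties of layer `i` (1 = top).
#' @param i layer index.
#' @export
layerProperties <- function(object, i) {
  stopifnot(is(object, "LayeredModel"))
  object@layers[[i]]
}

setMethod("show", "LayeredModel", function(object) {
  cat(sprintf("LayeredModel with %d layer(s), total thickness %g mm\n",
              nLayers(object), totalThickness(object)))
  for (i in seq_len(nLayers(object))) {
    p <- object@layers[[i]]
    cat(sprintf("  layer %d: %g mm, muA = %g, muSr = %g, g = %g, n = %g\n",
                i, object@thicknessMm[i], p@muA, p@muSr, p@g, p@n))
  }
})

#' Dual-fiber probe geometry
#'
#' One source and one detection fiber side by side at the probe tip. A photon
#' is collected when it crosses the tip plane moving back toward the probe,
#' inside the detector-fiber disc, with |direction cosine| at least
#' `acceptanceCosMin`.
#'
#' @slot fiberDiameterUm fiber core diameter (micrometres).
#' @slot separationUm centre-to-centre source-detector distance (micrometres).
#' @slot acceptanceCosMin minimum |cos| of the exit direction relative to the
#'   probe axis for collection, in `(0, 1]`.
#' @export
setClass("ProbeGeometry",
         representation(fiberDiameterUm = "numeric", separationUm = "numeric",
                        acceptanceCosMin = "numeric"))

setValidity("ProbeGeometry", function(object) {
  msg <- character()
  if (object@fiberDiameterUm <= 0) msg <- c(msg, "fiberDiameterUm must be > 0")
  if (object@separationUm < object@fiberDiameterUm)
    msg <- c(msg, "separationUm must be >= fiberDiameterUm")
  if (object@acceptanceCosMin <= 0 || object@acceptanceCosMin > 1)
    msg <- c(msg, "acceptanceCosMin must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct the probe geometry
#'
#' Defaults describe the needle probe used throughout: two 200 um fibers at
#' 200 um centre-to-centre separation. The acceptance cone is not specified by
#' the measurement geometry beyond "vertical to the surface", so it is a
#' configurable parameter with a documented default of 0.5.
#'
#' @param fiberDiameterUm fiber diameter (um), default 200.
#' @param separationUm centre-to-centre separation (um), default 200.
#' @param acceptanceCosMin minimum |cos| for collection, default 0.5.
#' @return A [ProbeGeometry-class] object.
#' @export
probeGeometry <- function(fiberDiameterUm = 200, separationUm = 200,
                          acceptanceCosMin = 0.5) {
  new("ProbeGeometry", fiberDiameterUm = as.numeric(fiberDiameterUm),
      separationUm = as.numeric(separationUm),
      acceptanceCosMin = as.numeric(acceptanceCosMin))
}

setMethod("show", "ProbeGeometry", function(object) {
  cat(sprintf(
    "ProbeGeometry: %g um fibers, %g um separation, acceptance |cos| >= %g\n",
    object@fiberDiameterUm, object@separationUm, object@acceptanceCosMin))
})

## ---------------------------------------------------------------------------
## Scan schedule and depth profile
## ---------------------------------------------------------------------------

#' Probe depth scan schedule
#'
#' Ordered probe depths H (mm from the top surface) at which reflectance is
#' simulated or measured.
#'
#' @slot depthsMm strictly increasing depths (mm).
#' @export
setClass("ScanSchedule", representation(depthsMm = "numeric"))

setValidity("ScanSchedule", function(object) {
  d <- object@depthsMm
  msg <- character()
  if (length(d) < 1L) msg <- c(msg, "schedule must contain at least one depth")
  if (any(!is.finite(d))) msg <- c(msg, "depths must be finite")
  else {
    if (any(d < 0)) msg <- c(msg, "depths must be >= 0")
    if (length(d) > 1L && any(diff(d) <= 0))
      msg <- c(msg, "depths must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a scan schedule
#'
#' @param depthsMm strictly increasing probe depths (mm).
#' @return A [ScanSchedule-class] object.
#' @export
scanSchedule <- function(depthsMm) new("ScanSchedule", depthsMm = as.numeric(depthsMm))

#' The insertion-study scan schedule
#'
#' 0.2 mm steps from 0 to 4 mm, then 0.1 mm steps from 4 to 6 mm while the
#' probe crosses the layer boundary (41 depths in total).
#'
#' @return A [ScanSchedule-class] object.
#' @export
insertionScanSchedule <- function() {
  scanSchedule(c(seq(0, 40, by = 2), seq(41, 60, by = 1)) / 10)
}

#' @describeIn scanSchedule schedule depths (mm).
#' @param object a `ScanSchedule` or `DepthProfile`.
#' @export
setGeneric("depths", function(object) standardGeneric("depths"))
#' @export
setMethod("depths", "ScanSchedule", function(object) object@depthsMm)

setMethod("show", "ScanSchedule", function(object) {
  d <- object@depthsMm
  cat(sprintf("ScanSchedule: %d depths from %g to %g mm\n",
              length(d), min(d), max(d)))
})

#' Reflectance-versus-depth profile
#'
#' Detected reflectance of the probe at each scheduled depth, either raw
#' (mean detected packet weight per launched photon) or normalized to the
#' first point.
#'
#' @slot depthMm probe depths (mm).
#' @slot intensity detected reflectance per depth.
#' @slot se Monte Carlo standard error per depth (NA when unknown, e.g. for
#'   measured profiles).
#' @slot nPhotons photons launched per depth (NA when not simulated).
#' @slot seed base RNG seed used for the scan (NA when not simulated).
#' @slot normalized logical; `TRUE` when intensities are normalized to the
#'   first point.
#' @export
setClass("DepthProfile",
         representation(depthMm = "numeric", intensity = "numeric",
                        se = "numeric", nPhotons = "numeric",
                        seed = "numeric", normalized = "logical"))

setValidity("DepthProfile", function(object) {
  msg <- character()
  n <- length(object@depthMm)
  if (length(object@intensity) != n)
    msg <- c(msg, "depthMm and intensity must have equal length")
  if (length(object@se) != n)
    msg <- c(msg, "se must have one entry per depth")
  if (n > 1L && any(diff(object@depthMm) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensity must be >= 0")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "normalized must be a logical scalar")
  else if (object@normalized && n >= 1L &&
           abs(object@intensity[1] - 1) > 1e-12)
    msg <- c(msg, "normalized profile must start at 1")
  if (length(msg)) msg else TRUE
})

#' Construct a depth profile
#'
#' @param depthMm probe depths (mm), strictly increasing.
#' @param intensity detected reflectance per depth.
#' @param se per-depth Monte Carlo standard error (optional).
#' @param nPhotons photons per depth (optional).
#' @param seed base seed (optional).
#' @param normalized whether `intensity` is normalized to its first point.
#' @return A [DepthProfile-class] object.
#' @export
depthProfile <- function(depthMm, intensity, se = rep(NA_real_, length(depthMm)),
                         nPhotons = NA_real_, seed = NA_real_,
                         normalized = FALSE) {
  new("DepthProfile", depthMm = as.numeric(depthMm),
      intensity = as.numeric(intensity), se = as.numeric(se),
      nPhotons = as.numeric(nPhotons), seed = as.numeric(seed),
      normalized = normalized)
}

#' @export
setMethod("depths", "DepthProfile", function(object) object@depthMm)

#' @describeIn depthProfile reflectance values accessor.
#' @param object a `DepthProfile`.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @export
setMethod("intensities", "DepthProfile", function(object) object@intensity)

#' @describeIn depthProfile per-depth Monte Carlo standard errors.
#' @export
setGeneric("profileSE", function(object) standardGeneric("profileSE"))
#' @export
setMethod("profileSE", "DepthProfile", function(object) object@se)

#' @describeIn depthProfile whether the profile is normalized to its first point.
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @export
setMethod("isNormalized", "DepthProfile", function(object) object@normalized)

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile: %d depths (%g-%g mm), %s\n",
              length(object@depthMm), min(object@depthMm), max(object@depthMm),
              if (object@normalized) "normalized to first point" else "raw"))
  if (!is.na(object@nPhotons))
    cat(sprintf("  simulated with %g photons/depth, seed %g\n",
                object@nPhotons, object@seed))
})

## ---------------------------------------------------------------------------
## Spectra and pattern factors
## ---------------------------------------------------------------------------

#' Reflectance spectrum
#'
#' A wavelength grid (nm) with reflectance intensities, either raw
#' spectrometer counts or normalized reflectance R.
#'
#' @slot wavelength strictly increasing wavelengths (nm).
#' @slot intensity finite intensities, one per wavelength.
#' @export
setClass("Spectrum",
         representation(wavelength = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@intensity))
    msg <- c(msg, "wavelength and intensity must have equal length")
  if (length(object@wavelength) > 1L && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a reflectance spectrum
#'
#' @param wavelength strictly increasing wavelengths (nm).
#' @param intensity intensities, one per wavelength.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- nirSpectrum(340:1020, rep(1, 681))
#' areaFactor(s)
#' @export
nirSpectrum <- function(wavelength, intensity) {
  new("Spectrum", wavelength = as.numeric(wavelength),
      intensity = as.numeric(intensity))
}

#' @describeIn nirSpectrum wavelength grid accessor (nm).
#' @param object a `Spectrum`.
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @export
setMethod("wavelengths", "Spectrum", function(object) object@wavelength)

#' @export
setMethod("intensities", "Spectrum", function(object) object@intensity)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %g-%g nm, intensity range [%g, %g]\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), min(object@intensity),
              max(object@intensity)))
})

#' Spectral pattern factors
#'
#' The scalar summaries used to classify the probe location: integrated area
#' (340-1020 nm), spectral peak, regression slope over 500-550 nm (times the
#' reporting scale) and, when available, the externally measured reduced
#' scattering coefficient.
#'
#' @slot area trapezoidal integral over the area window (intensity x nm).
#' @slot peak maximum intensity within the window.
#' @slot peakWavelength wavelength of the (first) maximum (nm).
#' @slot slope least-squares slope over the slope window, times the
#'   reporting scale.
#' @slot muSr reduced scattering coefficient (1/cm); NA when not supplied.
#' @export
setClass("PatternFactors",
         representation(area = "numeric", peak = "numeric",
                        peakWavelength = "numeric", slope = "numeric",
                        muSr = "numeric"))

setMethod("show", "PatternFactors", function(object) {
  cat(sprintf(
    "PatternFactors: area = %g, peak = %g (at %g nm), slope = %g, muSr = %g\n",
    object@area, object@peak, object@peakWavelength, object@slope, object@muSr))
})

#' @describeIn extractPatternFactors area accessor.
#' @param object a `PatternFactors` object.
#' @export
areaValue <- function(object) object@area
#' @describeIn extractPatternFactors peak accessor.
#' @export
peakValue <- function(object) object@peak
#' @describeIn extractPatternFactors slope accessor (reporting scale applied).
#' @export
slopeValue <- function(object) object@slope
#' @export
setMethod("muSr", "PatternFactors", function(object) object@muSr)

## ---------------------------------------------------------------------------
## Detection depth result
## ---------------------------------------------------------------------------

#' Detection-depth estimate
#'
#' Result of the deviation-onset rule: the first depth at which the normalized
#' profile leaves its flat-region band by more than `k` standard deviations
#' (persistently, up to the boundary), and the detection depth as the distance
#' from that onset to the known layer boundary.
#'
#' @slot onsetDepth onset depth (mm), a member of the profile grid.
#' @slot boundaryDepth layer boundary depth (mm).
#' @slot detectionDepth `boundaryDepth - onsetDepth` (mm).
#' @slot flatMean mean normalized intensity in the flat region.
#' @slot flatSd sample standard deviation in the flat region.
#' @slot flatRegion depth interval used as the flat region (mm).
#' @slot k deviation multiplier used.
#' @export
setClass("DetectionDepthResult",
         representation(onsetDepth = "numeric", boundaryDepth = "numeric",
                        detectionDepth = "numeric", flatMean = "numeric",
                        flatSd = "numeric", flatRegion = "numeric",
                        k = "numeric"))

setValidity("DetectionDepthResult", function(object) {
  if (object@detectionDepth < 0) "detectionDepth must be >= 0" else TRUE
})

setMethod("show", "DetectionDepthResult", function(object) {
  cat(sprintf(
    paste0("DetectionDepthResult: onset %g mm, boundary %g mm, ",
           "detection depth %g mm\n  flat region [%g, %g] mm: mean %.6g, ",
           "sd %.3g (k = %g)\n"),
    object@onsetDepth, object@boundaryDepth, object@detectionDepth,
    object@flatRegion[1], object@flatRegion[2], object@flatMean,
    object@flatSd, object@k))
})

#' @describeIn detectionDepth onset depth accessor (mm).
#' @param object a `DetectionDepthResult`.
#' @export
onsetDepth <- function(object) object@onsetDepth
#' @describeIn detectionDepth detection depth accessor (mm).
#' @export
detectionDepthValue <- function(object) object@detectionDepth

## ---------------------------------------------------------------------------
## Region summaries, ratio tables, alarm band
## ---------------------------------------------------------------------------

#' Per-region pattern-factor summary
#'
#' Mean, minimum and maximum of each pattern factor within the spongy, alarm
#' and compact regions.
#'
#' @slot table data.frame with columns `region`, `factor`, `mean`, `min`,
#'   `max`.
#' @export
setClass("RegionSummary", representation(table = "data.frame"))

setValidity("RegionSummary", function(object) {
  tb <- object@table
  need <- c("region", "factor", "mean", "min", "max")
  if (!all(need %in% names(tb)))
    return(sprintf("summary table needs columns %s", paste(need, collapse = ", ")))
  if (any(tb$min > tb$mean + 1e-12) || any(tb$mean > tb$max + 1e-12))
    return("each cell must satisfy min <= mean <= max")
  TRUE
})

#' @describeIn summarizeRegions the underlying summary data.frame.
#' @param object a `RegionSummary` (or `RatioTable`).
#' @export
setGeneric("summaryTable", function(object) standardGeneric("summaryTable"))
#' @export
setMethod("summaryTable", "RegionSummary", function(object) object@table)

setMethod("show", "RegionSummary", function(object) {
  cat("RegionSummary:\n")
  print(object@table, row.names = FALSE)
})

#' Ratio table for pattern-factor comparison
#'
#' The four separation ratios per pattern factor. `value` is a fraction;
#' `percent` is the same value times 100. Negative values indicate region
#' overlap and are kept (not clipped).
#'
#' @slot table data.frame with columns `ratio`, `factor`, `value`, `percent`.
#' @export
setClass("RatioTable", representation(table = "data.frame"))

setValidity("RatioTable", function(object) {
  if (!all(c("ratio", "factor", "value", "percent") %in% names(object@table)))
    return("ratio table needs columns ratio, factor, value, percent")
  if (any(!is.finite(object@table$value))) return("ratios must be finite")
  TRUE
})

#' @export
setMethod("summaryTable", "RatioTable", function(object) object@table)

setMethod("show", "RatioTable", function(object) {
  cat("RatioTable (percent):\n")
  tb <- object@table
  wide <- stats::reshape(tb[, c("ratio", "factor", "percent")],
                         direction = "wide", idvar = "ratio",
                         timevar = "factor")
  names(wide) <- sub("^percent\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
})

#' Alarm band for one pattern factor
#'
#' The closed interval of factor values that signals "probe within one
#' detection depth of the boundary": round-to-nearest-integer of the alarm
#' region's minimum and maximum.
#'
#' @slot factor pattern-factor name.
#' @slot lower lower band edge (factor units).
#' @slot upper upper band edge (factor units).
#' @export
setClass("AlarmBand",
         representation(factor = "character", lower = "numeric",
                        upper = "numeric"))

setValidity("AlarmBand", function(object) {
  if (object@lower >= object@upper) "band must satisfy lower < upper" else TRUE
})

setMethod("show", "AlarmBand", function(object) {
  cat(sprintf("AlarmBand (%s): alarm when value in [%g, %g]\n",
              object@factor, object@lower, object@upper))
})

#' @describeIn alarmBand band edges `c(lower, upper)`.
#' @param object an `AlarmBand`.
#' @export
bandLimits <- function(object) c(lower = object@lower, upper = object@upper)
#' @describeIn alarmBand the factor the band applies to.
#' @export
bandFactor <- function(object) object@factor

## ---------------------------------------------------------------------------
## Labeled synthetic dataset
## ---------------------------------------------------------------------------

#' Labeled synthetic insertion dataset
#'
#' Replicate-structured spectra over a depth schedule, with the true mixing
#' weight and the geometric region label at each depth. Labels follow the
#' depth rule: spongy for `depth < boundary - detectionDepth`, alarm for
#' depths from there up to (excluding) the boundary, compact at and below the
#' boundary.
#'
#' @slot wavelength shared wavelength grid (nm).
#' @slot depthMm scheduled depths (mm).
#' @slot region region label per depth.
#' @slot weight true mixing weight per depth, in `[0, 1]`.
#' @slot replicates list (one per depth) of wavelength-by-replicate matrices.
#' @slot averaged wavelength-by-depth matrix of replicate-averaged spectra.
#' @slot muSr replicate-averaged reduced scattering coefficient per depth.
#' @slot config the generator configuration used.
#' @slot seed RNG seed used.
#' @export
setClass("LabeledDataset",
         representation(wavelength = "numeric", depthMm = "numeric",
                        region = "character", weight = "numeric",
                        replicates = "list", averaged = "matrix",
                        muSr = "numeric", config = "list", seed = "numeric"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  nd <- length(object@depthMm)
  if (length(object@region) != nd || length(object@weight) != nd ||
      length(object@muSr) != nd || length(object@replicates) != nd ||
      ncol(object@averaged) != nd)
    msg <- c(msg, "per-depth slots must agree in length")
  if (any(object@weight < 0 | object@weight > 1))
    msg <- c(msg, "mixing weights must lie in [0, 1]")
  if (!all(object@region %in% c("spongy", "alarm", "compact")))
    msg <- c(msg, "regions must be spongy, alarm or compact")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("depths", "LabeledDataset", function(object) object@depthMm)

#' @describeIn generateDataset region label per depth.
#' @param object a `LabeledDataset`.
#' @export
regionLabels <- function(object) object@region
#' @describeIn generateDataset true mixing weight per depth.
#' @export
mixingWeights <- function(object) object@weight
#' @describeIn generateDataset replicate-averaged spectrum at depth index `i`.
#' @param i depth index.
#' @export
averagedSpectrum <- function(object, i) {
  nirSpectrum(object@wavelength, object@averaged[, i])
}
#' @describeIn generateDataset list of replicate [Spectrum-class] objects at
#'   depth index `i`.
#' @export
replicateSpectra <- function(object, i) {
  m <- object@replicates[[i]]
  lapply(seq_len(ncol(m)), function(j) nirSpectrum(object@wavelength, m[, j]))
}

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf(
    "LabeledDataset: %d depths (%g-%g mm), %d replicates/depth, seed %g\n",
    length(object@depthMm), min(object@depthMm), max(object@depthMm),
    ncol(object@replicates[[1]]), object@seed))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s x %d", names(table(object@region)),
                            as.integer(table(object@region))), collapse = ", ")))
})
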