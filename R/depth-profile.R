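## Detection-depth statistic on a reflectance-vs-depth profile: normalization
## to the first point, flat-region dispersion, k-sigma deviation onset with a
## persistence guard, and detection depth relative to the known boundary.

#' Normalize a depth profile to its first point
#'
#' @param profile a [DepthProfile-class].
#' @return The profile with every intensity divided by the first (so the first
#'   entry is 1) and standard errors rescaled accordingly. Already-normalized
#'   profiles are returned unchanged.
#' @examples
#' p <- depthProfile(c(0, 1, 2), c(2, 1, 0.5))
#' intensities(normalizeToFirst(p))
#' @export
setGeneric("normalizeToFirst", function(profile) standardGeneric("normalizeToFirst"))

#' @export
setMethod("normalizeToFirst", "DepthProfile", function(profile) {
  if (profile@normalized) return(profile)
  first <- profile@intensity[1]
  if (!is.finite(first) || first <= 0)
    stop("degenerate profile: first intensity must be positive")
  depthProfile(profile@depthMm, profile@intensity / first,
               se = profile@se / first, nPhotons = profile@nPhotons,
               seed = profile@seed, normalized = TRUE)
})

#' Flat-region mean and dispersion
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' profile intensities at depths inside the flat interval (inclusive).
#'
#' @param profile a [DepthProfile-class] (normally the normalized profile).
#' @param flatInterval length-2 depth interval (mm) taken as the flat region.
#' @return Named list with `mean`, `sd` and `n` (points used).
#' @export
flatRegionStats <- function(profile, flatInterval) {
  stopifnot(is(profile, "DepthProfile"), length(flatInterval) == 2L)
  inside <- profile@depthMm >= flatInterval[1] & profile@depthMm <= flatInterval[2]
  if (sum(inside) < 3L)
    stop("insufficient data: need at least 3 profile points in the flat interval")
  v <- profile@intensity[inside]
  list(mean = mean(v), sd = stats::sd(v), n = sum(inside))
}

#' Deviation-onset depth
#'
#' The smallest depth, searched in increasing depth beyond the flat interval,
#' at which the absolute deviation of the intensity from `flatMean` exceeds
#' `k * flatSd` and keeps exceeding it at every subsequent grid point up to
#' `boundaryMm` (persistence guard, so isolated noise spikes cannot trigger
#' the onset).
#'
#' @param profile a [DepthProfile-class], normalized.
#' @param flatMean,flatSd flat-region statistics (see [flatRegionStats()]).
#' @param k deviation multiplier, `> 0` (default 2).
#' @param after only depths strictly greater than this are searched (defaults
#'   to the first profile depth, i.e. search everywhere beyond the first
#'   point).
#' @param boundaryMm persistence horizon (defaults to the last profile depth).
#' @return Onset depth (mm), an element of the profile depth grid.
#' @export
deviationOnset <- function(profile, flatMean, flatSd, k = 2,
                           after = NULL, boundaryMm = NULL) {
  stopifnot(is(profile, "DepthProfile"))
  if (k <= 0) stop("k must be > 0")
  d <- profile@depthMm
  if (is.null(after)) after <- d[1]
  if (is.null(boundaryMm)) boundaryMm <- d[length(d)]
  idx <- which(d > after & d <= boundaryMm)
  if (!length(idx)) stop("no profile points beyond the flat interval")
  exceed <- abs(profile@intensity[idx] - flatMean) > k * flatSd
  persistent <- rev(cumprod(rev(exceed))) == 1
  if (!any(persistent))
    stop("no onset: profile never leaves the flat band persistently")
  d[idx[which(persistent)[1]]]
}

#' Detection depth from a reflectance-depth profile
#'
#' Normalizes the profile to its first point, estimates the flat-region mean
#' and standard deviation, finds the deviation onset (first marker) with the
#' `k`-sigma rule, and reports the detection depth as the distance from the
#' onset to the known layer boundary (second marker).
#'
#' @param profile a [DepthProfile-class] (raw or already normalized).
#' @param boundaryMm known layer-boundary depth (mm); must be a grid depth.
#' @param flatInterval depth interval (mm) treated as flat; default
#'   `c(0, 3.5)`, safely inside the flat zone of the two-layer bone scan.
#' @param k deviation multiplier (default 2).
#' @return A [DetectionDepthResult-class].
#' @examples
#' d <- c(seq(0, 4, 0.2), seq(4.1, 6, 0.1))
#' y <- ifelse(d < 4.4, 1, ifelse(d < 5, 1 - (d - 4.4) / 0.6 * 0.4, 0.6))
#' res <- detectionDepth(depthProfile(d, y), boundaryMm = 5)
#' detectionDepthValue(res)  # 0.6
#' @export
detectionDepth <- function(profile, boundaryMm, flatInterval = c(0, 3.5), k = 2) {
  stopifnot(is(profile, "DepthProfile"))
  norm <- normalizeToFirst(profile)
  d <- norm@depthMm
  if (!any(abs(d - boundaryMm) < 1e-9))
    stop("boundaryMm must be one of the profile depths")
  boundaryMm <- d[which.min(abs(d - boundaryMm))]
  fs <- flatRegionStats(norm, flatInterval)
  onset <- deviationOnset(norm, fs$mean, fs$sd, k = k,
                          after = flatInterval[2], boundaryMm = boundaryMm)
  new("DetectionDepthResult", onsetDepth = onset, boundaryDepth = boundaryMm,
      detectionDepth = round(boundaryMm - onset, 12), flatMean = fs$mean,
      flatSd = fs$sd, flatRegion = as.numeric(flatInterval), k = as.numeric(k))
}
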