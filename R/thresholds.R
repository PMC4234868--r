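## Region summaries, the four separation ratios, pattern-factor selection,
## alarm-band derivation, the alarm classifier and the group-separation test.

.FACTORS <- c("area", "mu_s_reduced", "peak", "slope")
.REGIONS <- c("spongy", "alarm", "compact")

.checkRatioInputs <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) stop("ratio inputs must be finite")
  if (a == 0) stop("division error: reference value is zero")
  invisible(TRUE)
}

#' Summarize pattern factors per region
#'
#' Mean, minimum and maximum of every pattern factor within the spongy, alarm
#' and compact regions of a labeled factor table.
#'
#' @param series data.frame with columns `region` and the factor columns
#'   `mu_s_reduced`, `peak`, `area`, `slope` (see [factorTable()]).
#' @return A [RegionSummary-class].
#' @export
summarizeRegions <- function(series) {
  stopifnot(is.data.frame(series), "region" %in% names(series))
  facs <- intersect(.FACTORS, names(series))
  if (!length(facs)) stop("series contains no pattern-factor columns")
  missing <- setdiff(.REGIONS, unique(series$region))
  if (length(missing))
    stop("incomplete labeling: no records for region(s) ",
         paste(missing, collapse = ", "))
  rows <- list()
  for (r in .REGIONS) {
    sub <- series[series$region == r, , drop = FALSE]
    for (f in facs) {
      v <- sub[[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, factor = f, mean = mean(v), min = min(v), max = max(v))
    }
  }
  new("RegionSummary", table = do.call(rbind, rows))
}

.summaryCell <- function(summary, region, factor, stat) {
  tb <- summary@table
  v <- tb[tb$region == region & tb$factor == factor, stat]
  if (length(v) != 1L)
    stop(sprintf("summary has no cell for region '%s', factor '%s'",
                 region, factor))
  v
}

#' Separation ratios between adjacent regions
#'
#' The four ratios quantifying how well one pattern factor separates the
#' spongy, alarm and compact regions. All are returned as fractions
#' (multiply by 100 for percent); all are invariant under a common positive
#' rescaling of their inputs. A negative value flags region overlap.
#'
#' * `ratio1 = (mean spongy - mean alarm) / mean spongy`
#' * `ratio2 = (mean alarm - mean compact) / mean alarm`
#' * `ratio3 = (min spongy - max alarm) / min spongy`
#' * `ratio4 = (min alarm - max compact) / min alarm`
#'
#' @param meanSpongy,meanAlarm,meanCompact region means of a factor.
#' @param minSpongy,maxAlarm,minAlarm,maxCompact region extremes of a factor.
#' @return The ratio as a fraction.
#' @examples
#' 100 * ratio1(185213.61, 106896.1)  # 42.28 percent
#' @export
ratio1 <- function(meanSpongy, meanAlarm) {
  .checkRatioInputs(meanSpongy, meanAlarm)
  (meanSpongy - meanAlarm) / meanSpongy
}

#' @rdname ratio1
#' @export
ratio2 <- function(meanAlarm, meanCompact) {
  .checkRatioInputs(meanAlarm, meanCompact)
  (meanAlarm - meanCompact) / meanAlarm
}

#' @rdname ratio1
#' @export
ratio3 <- function(minSpongy, maxAlarm) {
  .checkRatioInputs(minSpongy, maxAlarm)
  (minSpongy - maxAlarm) / minSpongy
}

#' @rdname ratio1
#' @export
ratio4 <- function(minAlarm, maxCompact) {
  .checkRatioInputs(minAlarm, maxCompact)
  (minAlarm - maxCompact) / minAlarm
}

#' Ratio table from a region summary
#'
#' Computes all four separation ratios for every factor in the summary.
#' Negative ratios (overlapping regions) are kept and reported with a warning.
#'
#' @param summary a [RegionSummary-class].
#' @return A [RatioTable-class].
#' @export
ratioTable <- function(summary) {
  stopifnot(is(summary, "RegionSummary"))
  facs <- unique(summary@table$factor)
  rows <- list()
  for (f in facs) {
    vals <- c(
      ratio1 = ratio1(.summaryCell(summary, "spongy", f, "mean"),
                      .summaryCell(summary, "alarm", f, "mean")),
      ratio2 = ratio2(.summaryCell(summary, "alarm", f, "mean"),
                      .summaryCell(summary, "compact", f, "mean")),
      ratio3 = ratio3(.summaryCell(summary, "spongy", f, "min"),
                      .summaryCell(summary, "alarm", f, "max")),
      ratio4 = ratio4(.summaryCell(summary, "alarm", f, "min"),
                      .summaryCell(summary, "compact", f, "max")))
    rows[[f]] <- data.frame(ratio = names(vals), factor = f,
                            value = unname(vals),
                            percent = unname(vals) * 100)
  }
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  if (any(tb$value < 0))
    warning("negative ratio(s): adjacent regions overlap for factor(s) ",
            paste(unique(tb$factor[tb$value < 0]), collapse = ", "))
  new("RatioTable", table = tb)
}

#' Select the alarm pattern factor
#'
#' Ranks the factors within each of the four ratios (rank 1 = largest ratio =
#' best separation) and selects the factor with the smallest rank sum, i.e.
#' the best joint separation across the mean-based ratios (1, 2) and the
#' extreme-based overlap checks (3, 4). Ties are broken deterministically by
#' factor name order and reported.
#'
#' @param ratios a [RatioTable-class].
#' @return list with `factor` (the selected name), `ranking` (data.frame of
#'   per-ratio ranks and the rank sum, best first) and `tie` (logical).
#' @export
selectAlarmFactor <- function(ratios) {
  stopifnot(is(ratios, "RatioTable"))
  tb <- ratios@table
  need <- paste0("ratio", 1:4)
  if (!all(need %in% tb$ratio))
    stop("incomplete ratio table: ratios 1-4 all required")
  facs <- sort(unique(tb$factor))
  rankmat <- sapply(need, function(r) {
    sub <- tb[tb$ratio == r, ]
    v <- sub$value[match(facs, sub$factor)]
    if (any(is.na(v))) stop("incomplete ratio table: missing factor cells")
    rank(-v, ties.method = "min")
  })
  rankSum <- rowSums(rankmat)
  ranking <- data.frame(factor = facs, rankmat, rankSum = rankSum,
                        row.names = NULL, check.names = FALSE)
  ranking <- ranking[order(ranking$rankSum, ranking$factor), ]
  rownames(ranking) <- NULL
  tie <- sum(rankSum == min(rankSum)) > 1L
  list(factor = ranking$factor[1], ranking = ranking, tie = tie)
}

# round half away from zero to the nearest integer (paper's band rounding)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Derive the alarm band for a factor
#'
#' The alarm band is the alarm region's minimum-to-maximum interval of the
#' selected factor, with endpoints rounded half-up to the nearest integer.
#'
#' @param summary a [RegionSummary-class].
#' @param factor factor name present in the summary (e.g. `"area"`).
#' @return An [AlarmBand-class].
#' @examples
#' ## Table of alarm-region extremes: area in [89782.84, 129871.7]
#' tab <- data.frame(region = c("spongy", "alarm", "alarm", "compact"),
#'                   area = c(2e5, 89782.84, 129871.7, 7e4))
#' band <- alarmBand(summarizeRegions(within(tab, {
#'   mu_s_reduced <- 1; peak <- 1; slope <- 1})), "area")
#' bandLimits(band)  # 89783, 129872
#' @export
alarmBand <- function(summary, factor) {
  stopifnot(is(summary, "RegionSummary"))
  lower <- .roundHalfUp(.summaryCell(summary, "alarm", factor, "min"))
  upper <- .roundHalfUp(.summaryCell(summary, "alarm", factor, "max"))
  if (lower >= upper)
    stop("degenerate band: alarm-region minimum and maximum coincide")
  new("AlarmBand", factor = factor, lower = lower, upper = upper)
}

#' Classify a measurement by the alarm band
#'
#' Strict three-way partition of the factor axis: values inside the closed
#' band are `alarm` (time to warn: the probe tip is within one detection
#' depth of the cortical boundary), values above are `spongy`, values below
#' are `compact`.
#'
#' @param value factor value(s).
#' @param band an [AlarmBand-class].
#' @return Character vector of region labels.
#' @examples
#' b <- new("AlarmBand", factor = "area", lower = 89783, upper = 129872)
#' classifyPoint(c(100000, 185214, 72473), b)
#' @export
classifyPoint <- function(value, band) {
  stopifnot(is(band, "AlarmBand"), all(is.finite(value)))
  ifelse(value > band@upper, "spongy",
         ifelse(value < band@lower, "compact", "alarm"))
}

#' Between-region separation test
#'
#' Tests, per pattern factor, whether the three regions differ. The default
#' is the Kruskal-Wallis rank-sum omnibus test (no normality assumption); a
#' one-way ANOVA is available as an alternative. A factor passes when
#' `p < alpha`.
#'
#' @param series labeled factor table (see [factorTable()]); every region
#'   needs at least 2 records.
#' @param test `"kruskal"` (default) or `"anova"`.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `factor`, `p`, `pass`.
#' @export
groupSeparation <- function(series, test = c("kruskal", "anova"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(is.data.frame(series), "region" %in% names(series))
  facs <- intersect(.FACTORS, names(series))
  counts <- table(factor(series$region, levels = .REGIONS))
  if (any(counts < 2L))
    stop("insufficient data: every region needs at least 2 records")
  g <- factor(series$region, levels = .REGIONS)
  res <- lapply(facs, function(f) {
    p <- if (test == "kruskal") {
      stats::kruskal.test(series[[f]], g)$p.value
    } else {
      stats::anova(stats::lm(series[[f]] ~ g))[["Pr(>F)"]][1]
    }
    data.frame(factor = f, p = p, pass = is.finite(p) && p < alpha)
  })
  do.call(rbind, res)
}

#' Full threshold derivation
#'
#' Convenience wrapper running the whole alarm-threshold pipeline on a labeled
#' factor table: region summary, ratio table, factor selection, alarm band for
#' the selected factor and the group-separation test.
#'
#' @inheritParams groupSeparation
#' @return list with elements `summary` ([RegionSummary-class]), `ratios`
#'   ([RatioTable-class]), `selection` (see [selectAlarmFactor()]), `band`
#'   ([AlarmBand-class]) and `separation` (data.frame).
#' @export
deriveThresholds <- function(series, test = c("kruskal", "anova"), alpha = 0.05) {
  summary <- summarizeRegions(series)
  ratios <- suppressWarnings(ratioTable(summary))
  selection <- selectAlarmFactor(ratios)
  band <- alarmBand(summary, selection$factor)
  separation <- groupSeparation(series, test = test, alpha = alpha)
  list(summary = summary, ratios = ratios, selection = selection,
       band = band, separation = separation)
}
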