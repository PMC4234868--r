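# Shared fixtures: the published per-region pattern-factor values
# (means in table2, extremes in table3) and small reusable objects.

table2Means <- function() {
  data.frame(
    factor = c("mu_s_reduced", "peak", "area", "slope"),
    spongy = c(16.91, 881.86, 185213.61, 5.64),
    alarm = c(14.71, 638.5, 106896.1, 3.07),
    compact = c(12.78, 463.91, 72472.75, 1.81))
}

table3Extremes <- function() {
  data.frame(
    factor = c("mu_s_reduced", "peak", "area", "slope"),
    spongyMin = c(16.33, 825, 170300.3, 4.87),
    alarmMax = c(15.51, 649.33, 129871.7, 4.18),
    alarmMin = c(14.6, 597, 89782.84, 2.43),
    compactMax = c(13.12, 503.33, 80788.38, 2.21))
}

# region summary carrying the published means and extremes (the mean of the
# extremes rows is irrelevant for the ratio/band computations, so min and max
# are the published values and the mean sits between them)
publishedRegionSummary <- function() {
  t2 <- table2Means()
  t3 <- table3Extremes()
  rows <- list()
  for (i in seq_len(nrow(t2))) {
    f <- t2$factor[i]
    rows[[length(rows) + 1L]] <- data.frame(
      region = "spongy", factor = f, mean = t2$spongy[i],
      min = t3$spongyMin[i], max = max(t2$spongy[i], t3$spongyMin[i]))
    rows[[length(rows) + 1L]] <- data.frame(
      region = "alarm", factor = f, mean = t2$alarm[i],
      min = t3$alarmMin[i], max = t3$alarmMax[i])
    rows[[length(rows) + 1L]] <- data.frame(
      region = "compact", factor = f, mean = t2$compact[i],
      min = min(t2$compact[i], t3$compactMax[i]), max = t3$compactMax[i])
  }
  new("RegionSummary", table = do.call(rbind, rows))
}

smallHomogeneousModel <- function(thicknessMm = 20) {
  layeredModel(list(opticalProperties(muA = 0.41, muSr = 17.23)), thicknessMm)
}

flatSpectrum <- function(value = 1) nirSpectrum(340:1020, rep(value, 681))
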