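syntheticSeries <- function(seed = 1, replicates = 20) {
  generateDataset(generatorConfig(replicates = replicates), seed = seed)
}

test_that("region summary gives per-region, per-factor mean/min/max", {
  tb <- data.frame(depth_mm = 1:6,
                   region = rep(c("spongy", "alarm", "compact"), each = 2),
                   mu_s_reduced = c(17, 16, 15, 14, 13, 12),
                   peak = c(900, 880, 650, 630, 470, 460),
                   area = c(19e4, 18e4, 11e4, 10e4, 7.3e4, 7.2e4),
                   slope = c(6, 5, 3.2, 2.9, 1.9, 1.7))
  s <- summarizeRegions(tb)
  st <- summaryTable(s)
  expect_equal(st$mean[st$region == "spongy" & st$factor == "area"], 18.5e4)
  expect_equal(st$min[st$region == "alarm" & st$factor == "peak"], 630)
  expect_equal(st$max[st$region == "compact" & st$factor == "slope"], 1.9)
  # label order invariance
  s2 <- summarizeRegions(tb[sample(nrow(tb)), ])
  expect_equal(summaryTable(s2), st)
  # single record per region: mean = min = max
  one <- tb[c(1, 3, 5), ]
  st1 <- summaryTable(summarizeRegions(one))
  expect_equal(st1$mean, st1$min)
  expect_equal(st1$mean, st1$max)
  expect_error(summarizeRegions(tb[tb$region != "alarm", ]),
               "incomplete labeling")
})

test_that("the four ratios implement their formulas and scale invariance", {
  expect_equal(ratio1(10, 10), 0)
  expect_equal(ratio2(10, 10), 0)
  expect_equal(ratio4(5, 5), 0)
  # overlap gives a negative, unclipped value
  expect_lt(ratio3(10, 12), 0)
  for (c in c(0.001, 1, 1e6)) {
    expect_equal(ratio1(c * 185213.61, c * 106896.1),
                 ratio1(185213.61, 106896.1))
    expect_equal(ratio3(c * 170300.3, c * 129871.7),
                 ratio3(170300.3, 129871.7))
  }
  expect_error(ratio1(0, 5), "zero")
})

test_that("factor selection minimizes the rank sum with a reported tie rule", {
  # a factor dominating all eight comparisons wins
  mk <- function(vals) {
    tb <- expand.grid(ratio = paste0("ratio", 1:4),
                      factor = c("area", "mu_s_reduced", "peak", "slope"),
                      stringsAsFactors = FALSE)
    tb$value <- vals[tb$factor]
    tb$percent <- tb$value * 100
    new("RatioTable", table = tb)
  }
  sel <- selectAlarmFactor(mk(c(area = 0.1, mu_s_reduced = 0.5, peak = 0.2,
                                slope = 0.3)))
  expect_equal(sel$factor, "mu_s_reduced")
  expect_false(sel$tie)
  # full tie resolved by factor name order and flagged
  tieSel <- selectAlarmFactor(mk(c(area = 0.2, mu_s_reduced = 0.2, peak = 0.2,
                                   slope = 0.2)))
  expect_equal(tieSel$factor, "area")
  expect_true(tieSel$tie)
  expect_error(selectAlarmFactor(new("RatioTable", table = data.frame(
    ratio = "ratio1", factor = "area", value = 0.1, percent = 10))),
    "incomplete")
})

test_that("alarm band rounds the alarm extremes half-up to integers", {
  s <- publishedRegionSummary()
  band <- alarmBand(s, "area")
  expect_equal(bandLimits(band), c(lower = 89783, upper = 129872))
  expect_equal(bandFactor(band), "area")
  # half-up rounding
  tb <- summaryTable(s)
  tb$min[tb$region == "alarm" & tb$factor == "peak"] <- 500.5
  tb$mean[tb$region == "alarm" & tb$factor == "peak"] <- 550
  tb$max[tb$region == "alarm" & tb$factor == "peak"] <- 600.49
  band2 <- alarmBand(new("RegionSummary", table = tb), "peak")
  expect_equal(unname(bandLimits(band2)), c(501, 600))
  # degenerate band
  tb$min[tb$region == "alarm" & tb$factor == "slope"] <- 3
  tb$max[tb$region == "alarm" & tb$factor == "slope"] <- 3.2
  expect_error(alarmBand(new("RegionSummary", table = tb), "slope"),
               "degenerate")
})

test_that("classification partitions the axis with inclusive band edges", {
  band <- new("AlarmBand", factor = "area", lower = 89783, upper = 129872)
  expect_equal(classifyPoint(c(89783, 129872, 100000), band),
               rep("alarm", 3))
  expect_equal(classifyPoint(129872.01, band), "spongy")
  expect_equal(classifyPoint(89782.99, band), "compact")
  # exactly one label for any finite value
  set.seed(2)
  v <- runif(200, 5e4, 2e5)
  lab <- classifyPoint(v, band)
  expect_true(all(lab %in% c("spongy", "alarm", "compact")))
  expect_equal(lab == "alarm", v >= 89783 & v <= 129872)
})

test_that("group separation passes on separated data and fails on null data", {
  ds <- syntheticSeries(seed = 11)
  tb <- factorTable(ds)
  rep <- groupSeparation(tb)
  expect_true(all(rep$pass))
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  # three literally identical groups: H = 0, p = 1, fail
  null <- data.frame(depth_mm = 1:18,
                     region = rep(c("spongy", "alarm", "compact"), each = 6),
                     mu_s_reduced = rep(1:6, 3), peak = rep(1:6, 3),
                     area = rep(1:6, 3), slope = rep(1:6, 3))
  repNull <- groupSeparation(null)
  expect_true(all(repNull$p > 0.99))
  expect_false(any(repNull$pass))
  # permuting labels of separated data destroys significance on average
  set.seed(10)
  pPerm <- replicate(20, {
    perm <- tb
    perm$region <- sample(perm$region)
    groupSeparation(perm)$p[3]
  })
  expect_gt(mean(pPerm), 0.2)
  few <- tb[c(1, 25, 41), ]
  expect_error(groupSeparation(few), "insufficient")
})

test_that("threshold derivation bundles summary, ratios, selection and band", {
  ds <- syntheticSeries(seed = 21)
  th <- deriveThresholds(factorTable(ds))
  expect_s4_class(th$summary, "RegionSummary")
  expect_s4_class(th$ratios, "RatioTable")
  expect_s4_class(th$band, "AlarmBand")
  expect_true(th$selection$factor %in%
                c("area", "mu_s_reduced", "peak", "slope"))
  expect_true(is.data.frame(th$separation))
})
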