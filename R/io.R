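## Config handling, delimited-text readers/writers and the pipeline runner.
## All artifacts are plain UTF-8 text with '.' decimals and LF endings;
## machine-readable outputs embed the package version, seed and a digest of
## the resolved configuration so equal-digest runs are byte-identical.

#' Read a two-column spectrum file
#'
#' Tab- or whitespace-delimited text with columns wavelength (nm) and
#' intensity; lines starting with `#` are ignored; an optional header line is
#' detected automatically.
#'
#' @param path file path.
#' @return A [Spectrum-class].
#' @export
readSpectrumFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  hasHeader <- length(first) > 0 &&
    is.na(suppressWarnings(as.numeric(strsplit(trimws(first[1]), "\\s+")[[1]][1])))
  tb <- utils::read.table(path, header = hasHeader, comment.char = "#")
  if (ncol(tb) < 2L) stop("spectrum file needs two columns")
  nirSpectrum(tb[[1]], tb[[2]])
}

#' Write a spectrum file
#'
#' @param spectrum a [Spectrum-class].
#' @param path output file path.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
writeSpectrumFile <- function(spectrum, path, comments = character()) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  writeLines("wavelength_nm\tintensity", con, sep = "\n")
  writeLines(paste(format(spectrum@wavelength, trim = TRUE, digits = 15),
                   format(spectrum@intensity, trim = TRUE, digits = 15),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read / write a depth profile file
#'
#' Delimited text with header columns `depth_mm`, `reflectance_raw`,
#' `reflectance_norm`, `se`, `n_photons`, `seed`; `#` lines are comments.
#'
#' @param path file path.
#' @return [readDepthProfile()]: the raw [DepthProfile-class].
#' @export
readDepthProfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.table(path, header = TRUE, comment.char = "#")
  depthProfile(tb$depth_mm, tb$reflectance_raw, se = tb$se,
               nPhotons = tb$n_photons[1], seed = tb$seed[1],
               normalized = FALSE)
}

#' @rdname readDepthProfile
#' @param profile a raw [DepthProfile-class].
#' @param comments optional `#` comment lines.
#' @return [writeDepthProfile()]: `path`, invisibly.
#' @export
writeDepthProfile <- function(profile, path, comments = character()) {
  stopifnot(is(profile, "DepthProfile"))
  norm <- normalizeToFirst(profile)
  tb <- data.frame(depth_mm = profile@depthMm,
                   reflectance_raw = profile@intensity,
                   reflectance_norm = norm@intensity,
                   se = profile@se,
                   n_photons = profile@nPhotons,
                   seed = profile@seed)
  .writeTsv(tb, path, comments)
}

#' Read / write a labeled factor table
#'
#' Delimited text with header columns `depth_mm`, `region`, `mu_s_reduced`,
#' `peak`, `area`, `slope` (the threshold-derivation input format).
#'
#' @param path file path.
#' @return [readFactorTable()]: the data.frame.
#' @export
readFactorTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("depth_mm", "region", "mu_s_reduced", "peak", "area", "slope")
  if (!all(need %in% names(tb)))
    stop("factor table needs columns ", paste(need, collapse = ", "))
  tb
}

#' @rdname readFactorTable
#' @param table the factor table data.frame.
#' @param comments optional `#` comment lines.
#' @export
writeFactorTable <- function(table, path, comments = character()) {
  .writeTsv(table, path, comments)
}

.writeTsv <- function(tb, path, comments = character()) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  writeLines(paste(names(tb), collapse = "\t"), con, sep = "\n")
  cols <- lapply(tb, function(col)
    if (is.numeric(col)) format(col, trim = TRUE, digits = 15) else as.character(col))
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Configuration
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' The fully resolved default configuration tree: the two-layer bone model and
#' probe geometry for the Monte Carlo stage, the insertion scan schedule, the
#' profile-analysis settings (flat region up to 3.5 mm, k = 2, boundary at
#' 5 mm), the spectral windows, the threshold options and the synthetic
#' generator defaults.
#'
#' @return Nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    mc = list(
      model = list(layers = list(
        list(mu_a = 0.41, mu_s_reduced = 17.23, g = 0.9, n = 1.38,
             thickness_mm = 5),
        list(mu_a = 0.21, mu_s_reduced = 12.02, g = 0.9, n = 1.38,
             thickness_mm = 2))),
      probe = list(fiber_diameter_um = 200, separation_um = 200,
                   acceptance_cos_min = 0.5),
      schedule = list(depths_mm = depths(insertionScanSchedule())),
      n_photons = 20000),
    profile = list(flat_max_mm = 3.5, k = 2, boundary_mm = 5),
    spectra = list(area_range_nm = c(340, 1020), slope_range_nm = c(500, 550),
                   slope_scale = 1000, expected_replicates = 20),
    thresholds = list(test = "kruskal", alpha = 0.05),
    synthetic = list(boundary_mm = 5, total_depth_mm = 6,
                     detection_depth_mm = 0.6, replicates = 20,
                     noise_sd = 0.02, slope_noise_sd = 4, mixing = "linear"))
}

# recursive merge of user values over defaults; unknown keys are an error
.mergeConfig <- function(default, user, path = "") {
  if (!is.list(default) || !is.list(user) || is.null(names(default)))
    return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    default[[k]] <- if (is.list(default[[k]]) && !is.null(names(default[[k]]))) {
      .mergeConfig(default[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  default
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills every omitted key from
#' [defaultConfig()], rejects unknown keys with the offending field path, and
#' validates every section by constructing the corresponding objects (so unit
#' and range violations are caught at load time).
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return The resolved configuration list (class `pipelineConfig`).
#' @export
loadConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .mergeConfig(defaultConfig(), user)
  # validation by construction
  .configModel(cfg)
  .configProbe(cfg)
  .configSchedule(cfg)
  .configGenerator(cfg)
  if (cfg$mc$n_photons < 1) stop("mc.n_photons must be >= 1")
  if (cfg$profile$k <= 0) stop("profile.k must be > 0")
  structure(cfg, class = c("pipelineConfig", "list"))
}

.configModel <- function(cfg) {
  layers <- cfg$mc$model$layers
  if (!length(layers)) stop("mc.model.layers: at least one layer required")
  props <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    tryCatch(
      opticalProperties(l$mu_a, l$mu_s_reduced, g = l$g, n = l$n),
      error = function(e) stop(sprintf("mc.model.layers[%d]: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  })
  th <- vapply(layers, function(l) as.numeric(l$thickness_mm), numeric(1))
  if (any(!is.finite(th)) || any(th <= 0))
    stop("mc.model.layers: thickness_mm must be positive")
  layeredModel(props, th)
}

.configProbe <- function(cfg) {
  p <- cfg$mc$probe
  probeGeometry(p$fiber_diameter_um, p$separation_um, p$acceptance_cos_min)
}

.configSchedule <- function(cfg) scanSchedule(cfg$mc$schedule$depths_mm)

.configGenerator <- function(cfg) {
  s <- cfg$synthetic
  generatorConfig(boundaryMm = s$boundary_mm, totalDepthMm = s$total_depth_mm,
                  detectionDepthMm = s$detection_depth_mm,
                  scheduleMm = cfg$mc$schedule$depths_mm,
                  replicates = s$replicates, noiseSd = s$noise_sd,
                  slopeNoiseSd = s$slope_noise_sd,
                  slopeScale = cfg$spectra$slope_scale, mixing = s$mixing)
}

#' Write a resolved configuration as YAML
#'
#' @param config a `pipelineConfig` (see [loadConfig()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.configDigest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

## ---------------------------------------------------------------------------
## Pipeline
## ---------------------------------------------------------------------------

.STAGES <- c("simulate", "generate-synthetic", "analyze-profile",
             "extract-factors", "derive-thresholds", "classify")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, each reading the previous stage's
#' declared artifacts from `outDir`:
#'
#' * `simulate` - Monte Carlo depth scan -> `profile.tsv`
#' * `analyze-profile` - detection depth from `profile.tsv` ->
#'   `profile_analysis.json`
#' * `generate-synthetic` - synthetic dataset -> `averaged_spectra.tsv`,
#'   `truth.tsv`
#' * `extract-factors` - pattern factors of the averaged spectra ->
#'   `factors.tsv`
#' * `derive-thresholds` - summary, ratios, selection, band, separation test
#'   -> `thresholds.json`, `region_summary.tsv`, `ratio_table.tsv`
#' * `classify` - labels every depth by the derived band ->
#'   `classified.tsv`
#'
#' A stage whose input artifact is missing raises a dependency error naming
#' the missing file. Every artifact embeds the package version, the seed and
#' the md5 digest of the resolved configuration.
#'
#' @param config a `pipelineConfig` from [loadConfig()].
#' @param stages character vector of stage names (a subset of the above, in
#'   dependency order).
#' @param outDir output directory (created if needed).
#' @return Invisibly, a named list of written file paths.
#' @export
runPipeline <- function(config = loadConfig(),
                        stages = c("generate-synthetic", "extract-factors",
                                   "derive-thresholds", "classify"),
                        outDir = ".") {
  bad <- setdiff(stages, .STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  digest <- .configDigest(config)
  stamp <- c(sprintf("pedicleNIRS %s",
                     as.character(utils::packageVersion("pedicleNIRS"))),
             sprintf("seed: %g", config$seed),
             sprintf("config_md5: %s", digest))
  paths <- list()
  need <- function(file) {
    p <- file.path(outDir, file)
    if (!file.exists(p))
      stop(sprintf("dependency error: required artifact '%s' is missing ", p),
           "(run its producing stage first)")
    p
  }

  for (stage in stages) {
    if (stage == "simulate") {
      model <- .configModel(config)
      probe <- .configProbe(config)
      sched <- .configSchedule(config)
      prof <- depthScan(model, probe, sched, config$mc$n_photons, config$seed)
      paths$profile <- writeDepthProfile(prof, file.path(outDir, "profile.tsv"),
                                         comments = stamp)
    } else if (stage == "analyze-profile") {
      prof <- readDepthProfile(need("profile.tsv"))
      res <- detectionDepth(prof, boundaryMm = config$profile$boundary_mm,
                            flatInterval = c(0, config$profile$flat_max_mm),
                            k = config$profile$k)
      out <- list(version = stamp[1], seed = config$seed, config_md5 = digest,
                  onset_depth_mm = res@onsetDepth,
                  boundary_depth_mm = res@boundaryDepth,
                  detection_depth_mm = res@detectionDepth,
                  flat_mean = res@flatMean, flat_sd = res@flatSd,
                  flat_region_mm = res@flatRegion, k = res@k)
      paths$profile_analysis <- file.path(outDir, "profile_analysis.json")
      jsonlite::write_json(out, paths$profile_analysis, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    } else if (stage == "generate-synthetic") {
      ds <- generateDataset(.configGenerator(config), seed = config$seed)
      avg <- data.frame(wavelength_nm = ds@wavelength, ds@averaged)
      names(avg)[-1] <- sprintf("depth_%g", ds@depthMm)
      paths$averaged_spectra <- .writeTsv(
        avg, file.path(outDir, "averaged_spectra.tsv"), comments = stamp)
      truth <- data.frame(depth_mm = ds@depthMm, region = ds@region,
                          mixing_weight = ds@weight, mu_s_reduced = ds@muSr)
      paths$truth <- .writeTsv(truth, file.path(outDir, "truth.tsv"),
                               comments = c(stamp, sprintf(
                                 "detection_depth_mm: %g",
                                 config$synthetic$detection_depth_mm)))
    } else if (stage == "extract-factors") {
      avg <- utils::read.table(need("averaged_spectra.tsv"), header = TRUE,
                               comment.char = "#", check.names = FALSE)
      truth <- utils::read.table(need("truth.tsv"), header = TRUE,
                                 comment.char = "#")
      wl <- avg[[1]]
      sp <- lapply(seq_len(ncol(avg) - 1L),
                   function(i) nirSpectrum(wl, avg[[i + 1L]]))
      tb <- factorTable(sp, depthMm = truth$depth_mm, muSr = truth$mu_s_reduced,
                        region = truth$region,
                        areaRange = config$spectra$area_range_nm,
                        slopeRange = config$spectra$slope_range_nm,
                        slopeScale = config$spectra$slope_scale)
      paths$factors <- writeFactorTable(tb, file.path(outDir, "factors.tsv"),
                                        comments = stamp)
    } else if (stage == "derive-thresholds") {
      tb <- readFactorTable(need("factors.tsv"))
      th <- deriveThresholds(tb, test = config$thresholds$test,
                             alpha = config$thresholds$alpha)
      paths$region_summary <- .writeTsv(
        summaryTable(th$summary), file.path(outDir, "region_summary.tsv"),
        comments = stamp)
      paths$ratio_table <- .writeTsv(
        summaryTable(th$ratios), file.path(outDir, "ratio_table.tsv"),
        comments = stamp)
      out <- list(version = stamp[1], seed = config$seed, config_md5 = digest,
                  selected_factor = th$selection$factor,
                  tie = th$selection$tie,
                  band = list(factor = th$band@factor,
                              lower = th$band@lower, upper = th$band@upper),
                  separation = th$separation)
      paths$thresholds <- file.path(outDir, "thresholds.json")
      jsonlite::write_json(out, paths$thresholds, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, dataframe = "rows")
    } else if (stage == "classify") {
      tb <- readFactorTable(need("factors.tsv"))
      th <- jsonlite::read_json(need("thresholds.json"), simplifyVector = TRUE)
      band <- new("AlarmBand", factor = th$band$factor,
                  lower = th$band$lower, upper = th$band$upper)
      tb$predicted <- classifyPoint(tb[[band@factor]], band)
      paths$classified <- .writeTsv(tb, file.path(outDir, "classified.tsv"),
                                    comments = stamp)
    }
  }
  invisible(paths)
}
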