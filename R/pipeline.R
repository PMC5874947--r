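#' Run one pipeline stage from a configuration list
#'
#' Single programmatic entry point behind the \code{exec/filmdose} command
#' line. The configuration is a named list with a \code{command} element
#' (\code{"calibrate"}, \code{"dosemap"}, \code{"organ-dose"},
#' \code{"procedure"} or \code{"simulate"}) plus the stage's parameters;
#' every report embeds a schema version, the package version, the
#' configuration hash and the seed, so re-running an identical
#' configuration reproduces an identical report. Inputs are never mutated.
#'
#' Stage parameters:
#' \describe{
#'   \item{calibrate}{\code{samples} (CSV path), \code{mode},
#'     \code{corr_manual}, \code{corr_abc}, \code{out} (curve JSON).}
#'   \item{dosemap}{\code{scan} (TIFF), \code{curve} (JSON), \code{roi}
#'     (ROI CSV), \code{dpi}, \code{channel},
#'     \code{unexposed_reference}, \code{out} (report JSON).}
#'   \item{organ-dose}{\code{slice_doses} (CSV side,index,dose_mgy[,se_mgy]),
#'     \code{slices} (CSV, default packaged table), \code{dap},
#'     \code{out}.}
#'   \item{procedure}{\code{log} (CSV), \code{factors} (CSV),
#'     \code{k_effective}, \code{tolerance_deg}, \code{out}.}
#'   \item{simulate}{\code{seed}, \code{spacing_mm},
#'     \code{entry_dose_per_dap}, \code{out} (directory: writes log.csv,
#'     ground_truth.json, scan TIFFs and the report).}
#' }
#'
#' @param config named list as described above; may also be the path of a
#'   YAML file holding that list. A \code{report} element names a JSON
#'   path the report is written to (distinct from each stage's own
#'   \code{out} output).
#' @return the report, invisibly (a named list; also written as JSON when
#'   \code{report} is given).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$command))
    stop("config must name a command (calibrate, dosemap, organ-dose, ",
         "procedure, simulate)")
  cmd <- config$command
  checkPaths(config)
  results <- switch(cmd,
    "calibrate" = stageCalibrate(config),
    "dosemap" = stageDoseMap(config),
    "organ-dose" = stageOrganDose(config),
    "procedure" = stageProcedure(config),
    "simulate" = stageSimulate(config),
    stop("unknown command: ", cmd))
  report <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("filmdose")),
    command = cmd,
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA,
    results = results)
  if (!is.null(config$report))
    jsonlite::write_json(report, config$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}

checkPaths <- function(config) {
  for (key in c("samples", "scan", "curve", "roi", "slice_doses",
                "slices", "log", "factors")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("input file for '", key, "' not found: ", p)
  }
  invisible(TRUE)
}

stageCalibrate <- function(cfg) {
  samples <- readCalibrationSamples(cfg$samples)
  corr <- detectorCorrection(cfg$corr_manual %||% 1.4, cfg$corr_abc %||% 2)
  curve <- fitCalibration(samples, cfg$mode %||% "abc", corr)
  if (!is.null(cfg$out)) writeCalibrationCurve(curve, cfg$out)
  list(mode = curve@mode, form = curve@form,
       dose_range_mgy = curve@doseRange, fit_rms_mgy = curve@fitRMS,
       n_samples = sum(samples$mode == curve@mode))
}

stageDoseMap <- function(cfg) {
  curve <- readCalibrationCurve(cfg$curve)
  scan <- loadScan(cfg$scan, dpi = cfg$dpi,
                   unexposedReference = cfg$unexposed_reference)
  dm <- scanToDoseMap(scan, curve, channel = cfg$channel %||% "red")
  rois <- readRoiTable(cfg$roi)
  per <- lapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    m <- roiMeanDose(dm, circularROI(r$center_x_mm, r$center_y_mm,
                                     r$radius_mm))
    list(slice_id = r$slice_id, mean_dose_mgy = m$mean, n_pixels = m$n,
         n_out_of_range = m$n_out_of_range)
  })
  list(pixel_spacing_mm = dm@pixelSpacing,
       out_of_range_pixels = sum(dm@outOfRange), rois = per)
}

stageOrganDose <- function(cfg) {
  sliceDoses <- utils::read.csv(cfg$slice_doses, stringsAsFactors = FALSE)
  slices <- if (is.null(cfg$slices)) randoBreastSlices() else
    readBreastSlices(cfg$slices)
  od <- organDose(sliceDoses, slices)
  out <- list(d_left_mgy = od@dLeft, d_right_mgy = od@dRight,
              d_overall_mgy = od@dOverall,
              relative_uncertainty = od@relativeUncertainty)
  if (!is.null(cfg$dap)) {
    out$dap_gycm2 <- cfg$dap
    out$cf_left <- conversionFactor(od@dLeft, cfg$dap)
    out$cf_right <- conversionFactor(od@dRight, cfg$dap)
    out$cf_overall <- conversionFactor(od@dOverall, cfg$dap)
  }
  out
}

stageProcedure <- function(cfg) {
  log <- readAcquisitionLog(cfg$log)
  table <- if (is.null(cfg$factors)) demoFactorTable() else
    readFactorTable(cfg$factors)
  est <- estimateBreastDose(log, table,
                            toleranceDeg = cfg$tolerance_deg %||% 6)
  k <- cfg$k_effective %||% 0.2
  list(total_dap_gycm2 = est@totalDap,
       d_left_mgy = est@dLeft, d_right_mgy = est@dRight,
       d_overall_mgy = est@dOverall,
       effective_dose_msv = effectiveDoseFromDap(est@totalDap, k),
       n_fallback = sum(est@perAcquisition$fallback_used),
       per_acquisition = est@perAcquisition)
}

stageSimulate <- function(cfg) {
  seed <- cfg$seed %||% 1
  sim <- generateMockProcedure(
    seed = seed, spacingMm = cfg$spacing_mm %||% 1,
    entryDosePerDap = cfg$entry_dose_per_dap %||% 8)
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sim$log, file.path(cfg$out, "log.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(slice_doses = sim$truth@sliceDoses,
           d_left_mgy = sim$truth@dLeft, d_right_mgy = sim$truth@dRight,
           d_overall_mgy = sim$truth@dOverall, dap_gycm2 = sim$truth@dap),
      file.path(cfg$out, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (key in names(sim$scans))
      writeScan(sim$scans[[key]], file.path(cfg$out,
                                            paste0("scan_", key, ".tif")))
  }
  list(seed = seed, total_dap_gycm2 = sim$truth@dap,
       true_d_left_mgy = sim$truth@dLeft,
       true_d_right_mgy = sim$truth@dRight,
       true_d_overall_mgy = sim$truth@dOverall,
       slice_doses = sim$truth@sliceDoses)
}
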