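# Umbrella pipeline: indices -> invert -> calibrate -> predict -> validate,
# with file artifacts per stage and a run manifest.

#' Pipeline configuration
#'
#' @param flux Path to the half-hourly flux CSV (see [read_flux_table()]).
#' @param reflectance Path to the 8-day reflectance CSV.
#' @param out_dir Output directory (created if absent).
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @param inversion [inversion_options()].
#' @param significance Calibration p-value gate.
#' @param night_par_threshold PAR threshold for the day/night split.
#' @param calibration_years,validation_years Optional integer vectors of
#'   calendar years: calibrate on the former, predict/validate on the latter.
#'   `NULL` uses all years for both (within-sample check).
#' @param fill Index gap-filling mode, `"linear"` or `"none"`.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the flux input was simulated).
#' @return List of class `nee_pipeline_config`.
#' @export
pipeline_config <- function(flux, reflectance, out_dir,
                            ca = 350,
                            inversion = inversion_options(),
                            significance = 0.05,
                            night_par_threshold = 5,
                            calibration_years = NULL,
                            validation_years = NULL,
                            fill = "linear",
                            seed = 1L) {
  structure(as.list(environment()), class = "nee_pipeline_config")
}

years_of <- function(ts) as.integer(format(ts, "%Y"))

#' Run the full modelling pipeline
#'
#' Stages: (1) vegetation-index computation with QC screening and
#' gap-filling; (2) per-window parameter inversion on the calibration years;
#' (3) regression calibration of parameters against indices and window-mean
#' environment; (4) parameter prediction and half-hourly NEE simulation for
#' the validation years; (5) validation report. Each stage writes its
#' artifact into `out_dir` (`indices.csv`, `parameters.csv`,
#' `candidates.csv`, `calibration.json`, `predicted_parameters.csv`,
#' `predictions.csv`, `windowed_r2.csv`, `report.json`, `manifest.json`);
#' each artifact is readable input for the next stage, so stages can also be
#' re-run individually via the exported functions or the CLI. Fails fast on
#' the first stage error with a stage-named message.
#'
#' @param cfg [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`indices`,
#'   `params`, `suite`, `predicted`, `report`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "nee_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_neeflux("stage_failure",
                   sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  flux <- stage("read", read_flux_table(cfg$flux))
  refl <- stage("read", read_reflectance_table(cfg$reflectance))

  indices <- stage("indices", build_index_series(refl, fill = cfg$fill))
  write_index_table(indices, file.path(cfg$out_dir, "indices.csv"))

  cal_years <- cfg$calibration_years %||% unique(years_of(flux$timestamp))
  val_years <- cfg$validation_years %||% unique(years_of(flux$timestamp))
  flux_cal <- flux[years_of(flux$timestamp) %in% cal_years, , drop = FALSE]
  flux_val <- flux[years_of(flux$timestamp) %in% val_years, , drop = FALSE]
  if (!nrow(flux_cal) || !nrow(flux_val)) {
    stop_neeflux("invalid_config", "year split leaves an empty partition")
  }

  params <- stage("invert",
                  invert_series(flux_cal, ca = cfg$ca, opts = cfg$inversion))
  write_parameter_table(params, file.path(cfg$out_dir, "parameters.csv"))

  suite <- stage("calibrate", {
    env <- window_environment(flux_cal)
    pred_tab <- merge(stats::setNames(indices[, c("date", "ndvi", "evi", "lswi")],
                                      c("window_start", "ndvi", "evi", "lswi")),
                      env, by = "window_start")
    cand <- fit_candidates(params, pred_tab)
    select_suite(cand, params, significance = cfg$significance)
  })
  utils::write.csv(suite$candidates,
                   file.path(cfg$out_dir, "candidates.csv"), row.names = FALSE)
  write_calibration(suite, file.path(cfg$out_dir, "calibration.json"))

  result <- stage("predict", {
    env_val <- window_environment(flux_val)
    pred_tab <- merge(stats::setNames(indices[, c("date", "ndvi", "evi", "lswi")],
                                      c("window_start", "ndvi", "evi", "lswi")),
                      env_val, by = "window_start")
    predicted <- predict_parameters(suite, pred_tab, opts = cfg$inversion)
    modeled <- simulate_series(flux_val, predicted, ca = cfg$ca)
    list(predicted = predicted, modeled = modeled)
  })
  write_parameter_table(result$predicted,
                        file.path(cfg$out_dir, "predicted_parameters.csv"))
  pred_out <- data.frame(
    timestamp = format(flux_val$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    nee_obs = flux_val$nee, nee_mod = result$modeled)
  utils::write.csv(pred_out, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)

  report <- stage("validate", {
    ok <- flux_val$valid
    validate(result$modeled[ok], flux_val$nee[ok], flux_val$par[ok],
             timestamps = flux_val$timestamp[ok],
             night_par_threshold = cfg$night_par_threshold)
  })
  if (!is.null(report$windowed)) {
    utils::write.csv(report$windowed,
                     file.path(cfg$out_dir, "windowed_r2.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    report[c("r2_all", "r2_day", "r2_night", "slope", "intercept",
             "n_all", "n_day", "n_night")],
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  manifest <- list(
    package = "neeflux",
    version = as.character(utils::packageVersion("neeflux")),
    seed = cfg$seed,
    ca = cfg$ca,
    significance = cfg$significance,
    night_par_threshold = cfg$night_par_threshold,
    calibration_years = cal_years,
    validation_years = val_years,
    inputs = list(flux = cfg$flux, reflectance = cfg$reflectance))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(indices = indices, params = params, suite = suite,
                 predicted = result$predicted, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
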