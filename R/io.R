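# Plain-CSV readers/writers for the pipeline's tables. Timestamps are
# ISO-8601 local standard time (no DST) read as UTC, matching flux-tower
# logger convention so PAR-based day/night logic stays solar-aligned.

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_neeflux("missing_column",
                 sprintf("%s missing column(s): %s", what,
                         paste(miss, collapse = ", ")))
  }
  invisible(df)
}

parse_timestamp <- function(x) {
  x <- gsub("T", " ", as.character(x))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M"))
  out
}

#' Read a half-hourly flux/meteorology table
#'
#' Expects CSV columns `timestamp`, `nee`, `par`, `t_air`, `t_soil`, `vwc`,
#' `precip` and optionally `valid` (assumed `TRUE` when absent). Records are
#' sorted, 30-min cadence is checked, and gaps in the cadence are repaired by
#' inserting rows flagged `valid = FALSE`. Timestamps not on the 30-min grid
#' trigger a warning (irregular cadence) but are kept.
#'
#' @param path CSV file path.
#' @return Data frame of half-hourly records (one per 30-min step of the
#'   covered span).
#' @export
read_flux_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("timestamp", "nee", "par", "t_air", "t_soil",
                        "vwc", "precip"), "flux table")
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts)) {
    stop_neeflux("unparseable_timestamp",
                 sprintf("%d unparseable timestamp(s), first at row %d",
                         sum(is.na(ts)), which(is.na(ts))[1]))
  }
  df$timestamp <- ts
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df$valid <- as.logical(df$valid)
  df <- df[order(df$timestamp), , drop = FALSE]
  if (anyDuplicated(df$timestamp)) {
    stop_neeflux("invalid_state", "duplicate timestamps in flux table")
  }
  off <- as.numeric(df$timestamp) %% 1800
  if (any(off != 0)) {
    warning(sprintf("%d timestamp(s) not on the 30-min grid (irregular cadence)",
                    sum(off != 0)), call. = FALSE)
  }
  grid <- seq(min(df$timestamp), max(df$timestamp), by = 1800)
  missing_ts <- setdiff(as.numeric(grid), as.numeric(df$timestamp))
  if (length(missing_ts)) {
    pad <- df[rep(NA_integer_, length(missing_ts)), , drop = FALSE]
    pad$timestamp <- as.POSIXct(missing_ts, origin = "1970-01-01", tz = "UTC")
    pad$valid <- FALSE
    df <- rbind(df, pad)
    df <- df[order(df$timestamp), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a flux table to CSV
#' @param flux Data frame as produced by [read_flux_table()] or
#'   [generate_scenario()].
#' @param path Output CSV path.
#' @export
write_flux_table <- function(flux, path) {
  out <- flux
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an 8-day surface-reflectance table
#'
#' Expects CSV columns `date`, `rho_blue`, `rho_red`, `rho_nir`, `rho_swir`,
#' `qc_ok`. Dates are snapped onto the 8-day composite grid check; duplicate
#' composite dates are an error. Records flagged `qc_ok` but carrying
#' reflectance outside \[0, 1\] are demoted to `qc_ok = FALSE` with a warning.
#'
#' @param path CSV file path.
#' @return Data frame of reflectance records sorted by date.
#' @export
read_reflectance_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("date", "rho_blue", "rho_red", "rho_nir", "rho_swir",
                        "qc_ok"), "reflectance table")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) {
    stop_neeflux("unparseable_timestamp", "unparseable composite date(s)")
  }
  if (anyDuplicated(df$date)) {
    stop_neeflux("invalid_state", "duplicate composite date in reflectance table")
  }
  df$qc_ok <- as.logical(df$qc_ok)
  off_grid <- df$date != slot_start(df$date)
  if (any(off_grid)) {
    warning(sprintf("%d composite date(s) not on the 8-day DOY 1,9,... grid",
                    sum(off_grid)), call. = FALSE)
  }
  bands <- c("rho_blue", "rho_red", "rho_nir", "rho_swir")
  bad <- df$qc_ok & rowSums(sapply(bands, function(b) {
    is.na(df[[b]]) | df[[b]] < 0 | df[[b]] > 1
  })) > 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with reflectance outside [0,1] demoted to qc_ok = FALSE",
                    sum(bad)), call. = FALSE)
    df$qc_ok[bad] <- FALSE
  }
  df[order(df$date), , drop = FALSE]
}

#' Write a reflectance table to CSV
#' @param refl Reflectance data frame.
#' @param path Output CSV path.
#' @export
write_reflectance_table <- function(refl, path) {
  utils::write.csv(refl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write an inverted-parameter table
#'
#' Columns: `window_start`, `alpha0`, `se_alpha0`, `gx`, `se_gx`, `b0`,
#' `se_b0`, `b`, `se_b`, `n_obs`, `rss`, `converged`.
#'
#' @param path CSV path.
#' @return Data frame keyed by `window_start`.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("window_start", "alpha0", "gx", "b0", "b"),
                  "parameter table")
  df$window_start <- as.Date(df$window_start)
  if ("converged" %in% names(df)) df$converged <- as.logical(df$converged)
  df
}

#' @rdname read_parameter_table
#' @param params Parameter data frame.
#' @export
write_parameter_table <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write index series
#' @param path CSV path.
#' @return Data frame `date`, `ndvi`, `evi`, `lswi`, `filled`.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("date", "ndvi", "evi", "lswi"), "index table")
  df$date <- as.Date(df$date)
  if ("filled" %in% names(df)) df$filled <- as.logical(df$filled)
  df
}

#' @rdname read_index_table
#' @param indices Index data frame.
#' @export
write_index_table <- function(indices, path) {
  utils::write.csv(indices, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save or load a calibration as structured JSON
#'
#' @param suite `nee_calibration` object.
#' @param path JSON file path.
#' @export
write_calibration <- function(suite, path) {
  stopifnot(inherits(suite, "nee_calibration"))
  jsonlite::write_json(
    list(significance = suite$significance,
         functions = suite$functions,
         candidates = suite$candidates),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  funs <- lapply(x$functions, function(f) {
    f$predictor <- if (is.null(f$predictor)) NA_character_ else f$predictor
    for (fld in c("intercept", "slope", "r2", "p"))
      if (is.null(f[[fld]])) f[[fld]] <- NA_real_
    f
  })
  structure(list(functions = funs,
                 candidates = as.data.frame(x$candidates),
                 significance = x$significance),
            class = "nee_calibration")
}
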