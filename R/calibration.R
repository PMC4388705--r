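# Regression calibration: relate inverted parameters to vegetation indices
# and window-mean environment, select the best predictor per parameter, and
# predict parameter trajectories from the selected linear maps.

VI_PREDICTORS  <- c("ndvi", "evi", "lswi")
ENV_PREDICTORS <- c("t_air", "t_soil", "vwc")

# which predictors may serve each parameter: the photosynthesis pair and the
# base respiration rate track canopy state (vegetation indices); the
# temperature sensitivity b tracks environment, not greenness
default_allowed_predictors <- function() {
  list(alpha0 = VI_PREDICTORS, gx = VI_PREDICTORS, b0 = VI_PREDICTORS,
       b = ENV_PREDICTORS)
}

#' Window-mean environment from half-hourly flux records
#'
#' Per 8-day slot means of air temperature, soil temperature and volumetric
#' soil water content over valid records, for use as regression predictors
#' aligned with the inversion windows.
#'
#' @param flux Data frame with `timestamp`, `t_air`, `t_soil`, `vwc` and
#'   optionally logical `valid`.
#' @return Data frame: `window_start`, `t_air`, `t_soil`, `vwc`.
#' @export
window_environment <- function(flux) {
  v <- if ("valid" %in% names(flux)) flux$valid else rep(TRUE, nrow(flux))
  dat <- flux[v, , drop = FALSE]
  ws <- slot_start(dat$timestamp)
  out <- stats::aggregate(
    dat[, intersect(c("t_air", "t_soil", "vwc"), names(dat)), drop = FALSE],
    by = list(window_start = ws), FUN = mean, na.rm = TRUE)
  out[order(out$window_start), , drop = FALSE]
}

#' Fit all parameter-by-predictor simple linear regressions
#'
#' Ordinary least-squares regression of each inverted parameter on each
#' candidate predictor, using converged windows only. `r2` is the squared
#' Pearson correlation and `p` the two-sided significance of the slope.
#'
#' @param params Parameter table from [invert_series()].
#' @param predictors Data frame keyed by `window_start` with any of the
#'   columns `ndvi`, `evi`, `lswi`, `t_air`, `t_soil`, `vwc` (merge the
#'   output of [build_index_series()] -- rename `date` to `window_start` --
#'   with [window_environment()]).
#' @return Candidate table: `parameter`, `predictor`, `slope`, `intercept`,
#'   `r2`, `p`, `n`.
#' @export
fit_candidates <- function(params, predictors) {
  preds <- intersect(c(VI_PREDICTORS, ENV_PREDICTORS), names(predictors))
  if (!length(preds)) {
    stop_neeflux("missing_column", "predictors carry no known predictor column")
  }
  dat <- merge(params[params$converged, , drop = FALSE], predictors,
               by = "window_start")
  rows <- list()
  for (pm in PARAM_NAMES) {
    for (pr in preds) {
      cc <- stats::complete.cases(dat[[pm]], dat[[pr]])
      n <- sum(cc)
      if (n < 3) next
      fit <- stats::lm(dat[[pm]][cc] ~ dat[[pr]][cc])
      sm <- suppressWarnings(summary(fit)) # zero-residual fits are legitimate
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pm, predictor = pr,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        r2 = sm$r.squared,
        p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
        n = n)
    }
  }
  if (!length(rows)) {
    stop_neeflux("insufficient_pairs",
                 "fewer than 3 aligned parameter/predictor pairs")
  }
  do.call(rbind, rows)
}

#' Select the best predictor per parameter
#'
#' Per parameter, keeps the admissible candidate with the highest `r2` among
#' those significant at `significance`. If no admissible candidate is
#' significant, the parameter falls back to a constant: the median of its
#' converged inverted values (flagged `fallback = TRUE`).
#'
#' @param candidates Candidate table from [fit_candidates()].
#' @param params Parameter table (used for the constant fallback).
#' @param significance Two-sided p-value gate, default 0.05.
#' @param allowed Named list of admissible predictors per parameter; the
#'   default admits vegetation indices for `alpha0`, `gx`, `b0` and
#'   environment variables for `b`.
#' @return Object of class `nee_calibration`: per-parameter linear maps plus
#'   the full candidate table.
#' @export
select_suite <- function(candidates, params, significance = 0.05,
                         allowed = default_allowed_predictors()) {
  funs <- list()
  for (pm in PARAM_NAMES) {
    cand <- candidates[candidates$parameter == pm &
                         candidates$predictor %in% allowed[[pm]] &
                         !is.na(candidates$p) &
                         candidates$p < significance, , drop = FALSE]
    if (nrow(cand)) {
      best <- cand[which.max(cand$r2), ]
      funs[[pm]] <- list(parameter = pm, predictor = best$predictor,
                         intercept = best$intercept, slope = best$slope,
                         r2 = best$r2, p = best$p, n = best$n,
                         fallback = FALSE)
    } else {
      const <- stats::median(params[[pm]][params$converged], na.rm = TRUE)
      funs[[pm]] <- list(parameter = pm, predictor = NA_character_,
                         intercept = const, slope = 0,
                         r2 = NA_real_, p = NA_real_,
                         n = sum(params$converged), fallback = TRUE)
    }
  }
  structure(list(functions = funs, candidates = candidates,
                 significance = significance),
            class = "nee_calibration")
}

#' @export
print.nee_calibration <- function(x, ...) {
  cat("NEE model calibration (significance gate p <",
      format(x$significance), ")\n")
  for (f in x$functions) {
    if (f$fallback) {
      cat(sprintf("  %-6s = %.4g  [constant fallback: no significant predictor]\n",
                  f$parameter, f$intercept))
    } else {
      cat(sprintf("  %-6s = %.4g %+.4g * %-6s (r2 = %.3f, p = %.2g, n = %d)\n",
                  f$parameter, f$intercept, f$slope, f$predictor, f$r2,
                  f$p, f$n))
    }
  }
  invisible(x)
}

#' Predict parameter trajectories from a calibration
#'
#' Applies each parameter's selected linear map to the aligned 8-day
#' predictor series and clips the result to the inversion bounds.
#'
#' @param suite `nee_calibration` from [select_suite()].
#' @param predictors 8-day predictor series keyed by `window_start` (gap
#'   filled: slots with a missing selected predictor raise an error).
#' @param opts [inversion_options()] supplying the clipping bounds.
#' @return Data frame: `window_start`, `alpha0`, `gx`, `b0`, `b`.
#' @export
predict_parameters <- function(suite, predictors,
                               opts = inversion_options()) {
  stopifnot(inherits(suite, "nee_calibration"))
  out <- data.frame(window_start = as.Date(predictors$window_start))
  for (pm in PARAM_NAMES) {
    f <- suite$functions[[pm]]
    if (f$fallback) {
      val <- rep(f$intercept, nrow(predictors))
    } else {
      x <- predictors[[f$predictor]]
      if (is.null(x) || anyNA(x)) {
        stop_neeflux("missing_predictor",
                     sprintf("predictor '%s' for %s missing or incomplete",
                             f$predictor, pm))
      }
      val <- f$intercept + f$slope * x
    }
    out[[pm]] <- pmin(pmax(val, opts$lower[[pm]]), opts$upper[[pm]])
  }
  out
}
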