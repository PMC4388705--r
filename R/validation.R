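# Forward prediction of half-hourly NEE from windowed parameters and scoring
# of modeled vs observed series (overall, day/night, per 8-day window).

#' Simulate half-hourly NEE from windowed parameters
#'
#' Evaluates the forward model ([nee()]) at every record's drivers using the
#' parameter set of the 8-day window containing its timestamp.
#'
#' @param flux Data frame with `timestamp`, `par`, `t_air`, `t_soil`.
#' @param params Data frame keyed by `window_start` with columns `alpha0`,
#'   `gx`, `b0`, `b` (e.g. from [predict_parameters()] or [invert_series()]);
#'   every record's slot must be present.
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @return Numeric vector of modeled NEE aligned with `flux` rows (negative =
#'   uptake). Rows whose window has `NA` parameters give `NA`.
#' @export
simulate_series <- function(flux, params, ca = 350) {
  ws <- slot_start(flux$timestamp)
  i <- match(ws, as.Date(params$window_start))
  if (anyNA(i)) {
    stop_neeflux("unmapped_timestamp",
                 sprintf("%d record(s) fall outside the supplied windows (first: %s)",
                         sum(is.na(i)), format(min(ws[is.na(i)]))))
  }
  nee(flux$par, flux$t_air, flux$t_soil,
      params$alpha0[i], params$gx[i], params$b0[i], params$b[i], ca)
}

r2_pearson <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  if (sum(cc) < 3) return(NA_real_)
  if (stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) return(NA_real_)
  stats::cor(x[cc], y[cc])^2
}

#' Score modeled against observed NEE
#'
#' R-squared is the squared Pearson correlation of modeled vs observed (the
#' coefficient of determination of the modeled~observed linear regression),
#' so it is invariant to affine miscalibration; the regression slope and
#' intercept report that miscalibration separately. Day and night strata are
#' split at a PAR threshold; a windowed R-squared series over the 8-day slots
#' is included when timestamps are given.
#'
#' @param modeled,observed Aligned numeric NEE series.
#' @param par Aligned PAR series (day/night split).
#' @param timestamps Optional aligned POSIXct; enables the windowed series.
#' @param night_par_threshold Night is `par < threshold`,
#'   micromol m^-2 s^-1 (default 5, flux-community convention).
#' @param min_window_pairs Minimum complete pairs for a windowed entry
#'   (default 10).
#' @return Object of class `nee_validation`: `r2_all`, `r2_day`, `r2_night`,
#'   `slope`, `intercept` (modeled ~ observed), `n_all`, `n_day`, `n_night`,
#'   and `windowed` (data frame `window_start`, `r2`, `n`).
#' @export
validate <- function(modeled, observed, par, timestamps = NULL,
                     night_par_threshold = 5, min_window_pairs = 10) {
  stopifnot(length(modeled) == length(observed),
            length(par) == length(observed))
  cc <- stats::complete.cases(modeled, observed, par)
  if (sum(cc) < 3) {
    stop_neeflux("insufficient_pairs", "fewer than 3 complete pairs overall")
  }
  m <- modeled[cc]; o <- observed[cc]; p <- par[cc]
  night <- p < night_par_threshold
  fit <- stats::lm(m ~ o)
  windowed <- NULL
  if (!is.null(timestamps)) {
    ws <- slot_start(timestamps[cc])
    windowed <- do.call(rbind, lapply(split(seq_along(ws), ws), function(ii) {
      if (length(ii) < min_window_pairs) return(NULL)
      data.frame(window_start = ws[ii[1]], r2 = r2_pearson(m[ii], o[ii]),
                 n = length(ii))
    }))
    if (!is.null(windowed)) rownames(windowed) <- NULL
  }
  structure(list(
    r2_all = r2_pearson(m, o),
    r2_day = r2_pearson(m[!night], o[!night]),
    r2_night = r2_pearson(m[night], o[night]),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_all = length(m), n_day = sum(!night), n_night = sum(night),
    night_par_threshold = night_par_threshold,
    windowed = windowed
  ), class = "nee_validation")
}

#' @export
print.nee_validation <- function(x, ...) {
  cat("NEE model validation (modeled vs observed)\n")
  cat(sprintf("  overall: R2 = %.3f, slope = %.3f, intercept = %.3f, N = %d\n",
              x$r2_all, x$slope, x$intercept, x$n_all))
  cat(sprintf("  daytime: R2 = %.3f (N = %d);  nighttime: R2 = %.3f (N = %d)\n",
              x$r2_day, x$n_day, x$r2_night, x$n_night))
  if (!is.null(x$windowed)) {
    cat(sprintf("  windowed series: %d 8-day entries, median R2 = %.3f\n",
                nrow(x$windowed), stats::median(x$windowed$r2, na.rm = TRUE)))
  }
  invisible(x)
}
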