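# Synthetic flux-tower + reflectance scenario generator.
#
# The defaults emulate a high-elevation alpine steppe-meadow site: strong
# radiation (clear-sky PAR peaking above 2000 micromol m^-2 s^-1), low annual
# mean air temperature with a large diurnal cycle, a short monsoon-season
# growing period peaking in early August, and vegetation indices rising from a
# sparse-canopy baseline to a modest summer maximum. Window-level "true"
# parameters are linear functions of the vegetation indices / soil
# temperature (plus noise), and half-hourly NEE is the forward model plus
# Gaussian observation noise, so every downstream stage has a known truth.

#' Scenario configuration for the synthetic generator
#'
#' All amplitudes are non-negative; dates must span at least one 8-day slot.
#' Temperatures in degrees C, PAR in micromol m^-2 s^-1, VWC in m^3 m^-3,
#' fluxes in micromol CO2 m^-2 s^-1.
#'
#' @param start,end Period covered (dates, inclusive).
#' @param latitude Site latitude, degrees N (sets daylength and sun angle).
#' @param par_max Clear-sky PAR at solar elevation 90 degrees; actual noon
#'   PAR is `par_max * sin(noon solar elevation)`.
#' @param t_air_mean,t_air_seas_amp Annual mean and seasonal semi-amplitude
#'   of daily-mean air temperature.
#' @param t_air_diurnal_amp Diurnal semi-amplitude of air temperature.
#' @param t_air_synoptic_sd Standard deviation of day-to-day (synoptic)
#'   air-temperature anomalies, modelled as a daily AR(1) process; the soil
#'   sees a damped, smoothed version of them.
#' @param t_air_peak_doy Day of year of the seasonal temperature maximum.
#' @param t_soil_damp_seas,t_soil_damp_diurnal Damping of the seasonal and
#'   diurnal air-temperature cycles at 5 cm soil depth.
#' @param t_soil_lag_days Seasonal phase lag of soil temperature, days.
#' @param t_soil_offset Additive offset of mean soil over mean air
#'   temperature.
#' @param ndvi_base,ndvi_amp,lswi_base,lswi_amp Baseline and seasonal
#'   amplitude of the NDVI and LSWI target curves. Reflectance bands are
#'   constructed to reproduce these two curves exactly (red and blue are held
#'   at fixed baselines, NIR is solved from NDVI, SWIR from LSWI); EVI is
#'   emergent from the constructed bands.
#' @param lswi_lead_days Phase lead of the LSWI curve over the greenness
#'   curve, days. LSWI tracks canopy/surface water, which rises with monsoon
#'   onset ahead of peak greenness; a non-zero lead also keeps the index
#'   series from being perfectly collinear (real VI series share a season but
#'   differ in magnitude and phase).
#' @param season_start_doy,season_peak_doy,season_end_doy Green-up,
#'   peak and senescence timing of the double-logistic season shape.
#' @param rho_red_base,rho_blue_base Fixed red/blue band reflectances.
#' @param map_alpha0,map_gx,map_b0,map_b Generating linear maps
#'   `c(intercept, slope, sd)`: `alpha0 ~ LSWI`, `gx ~ EVI`, `b0 ~ EVI`,
#'   `b ~ window-mean soil temperature`, each with Gaussian window-level
#'   noise of the given sd.
#' @param nee_noise_sd Half-hourly Gaussian observation noise on NEE.
#' @param qc_fail_frac Fraction of reflectance composites randomly corrupted
#'   and flagged `qc_ok = FALSE` (exercises gap-filling).
#' @param drought Logical: impose a dry spell with soil-moisture suppression
#'   of GPP (a process the forward model does not represent).
#' @param drought_start_doy,drought_end_doy Dry-spell span.
#' @param gpp_suppression Multiplier (< 1) applied to generated GPP in
#'   drought windows.
#' @param vwc_base,vwc_amp Baseline and seasonal amplitude of soil water
#'   content.
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @return A list of class `nee_scenario_config`.
#' @export
scenario_config <- function(start = "2007-01-01", end = "2007-12-31",
                            latitude = 30.5,
                            par_max = 2200,
                            t_air_mean = 1.3, t_air_seas_amp = 10.5,
                            t_air_diurnal_amp = 8, t_air_peak_doy = 205,
                            t_air_synoptic_sd = 2.5,
                            t_soil_damp_seas = 0.7, t_soil_damp_diurnal = 0.3,
                            t_soil_lag_days = 8, t_soil_offset = 1,
                            ndvi_base = 0.12, ndvi_amp = 0.38,
                            lswi_base = -0.05, lswi_amp = 0.30,
                            lswi_lead_days = 12,
                            season_start_doy = 140, season_peak_doy = 215,
                            season_end_doy = 290,
                            rho_red_base = 0.10, rho_blue_base = 0.05,
                            map_alpha0 = c(intercept = 0.006, slope = 0.08, sd = 0.0008),
                            map_gx = c(intercept = 0.004, slope = 0.06, sd = 0.0008),
                            map_b0 = c(intercept = 0.30, slope = 5, sd = 0.08),
                            map_b = c(intercept = 0.135, slope = -0.004, sd = 0.004),
                            nee_noise_sd = 0.5,
                            qc_fail_frac = 0,
                            drought = FALSE,
                            drought_start_doy = 185, drought_end_doy = 245,
                            gpp_suppression = 0.4,
                            vwc_base = 0.08, vwc_amp = 0.22,
                            seed = 42) {
  cfg <- as.list(environment())
  amps <- c(par_max, t_air_seas_amp, t_air_diurnal_amp, ndvi_amp, lswi_amp,
            vwc_amp, nee_noise_sd)
  if (any(amps < 0)) stop_neeflux("invalid_config", "amplitudes must be >= 0")
  if (qc_fail_frac < 0 || qc_fail_frac >= 1) {
    stop_neeflux("invalid_config", "qc_fail_frac must be in [0, 1)")
  }
  if (as.Date(end) - as.Date(start) < 7) {
    stop_neeflux("invalid_config", "scenario must span at least one 8-day slot")
  }
  for (m in c("map_alpha0", "map_gx", "map_b0", "map_b")) {
    v <- cfg[[m]]
    if (length(v) != 3 || v[[3]] < 0) {
      stop_neeflux("invalid_config",
                   sprintf("%s must be c(intercept, slope, sd >= 0)", m))
    }
  }
  structure(cfg, class = "nee_scenario_config")
}

# double-logistic phenology shape, normalized to max 1 over the year
season_shape <- function(doy, cfg) {
  raw <- function(d) {
    stats::plogis(0.12 * (d - cfg$season_start_doy)) *
      stats::plogis(-0.12 * (d - cfg$season_end_doy))
  }
  raw(doy) / raw(cfg$season_peak_doy)
}

solar_declination <- function(doy) {
  23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
}

# sine of solar elevation at fractional hour h (local solar time)
sin_elevation <- function(doy, hour, lat_deg) {
  lat <- lat_deg * pi / 180
  dec <- solar_declination(doy)
  H <- pi * (hour - 12) / 12
  sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(H)
}

drought_windows <- function(slots, cfg) {
  doy <- as.integer(format(slots, "%j"))
  cfg$drought & doy + 7 >= cfg$drought_start_doy & doy <= cfg$drought_end_doy
}

# clean (pre-corruption) target VI curves per 8-day slot; EVI is emergent
# from the reflectance construction, not an independent target
scenario_vi_curves <- function(slots, cfg) {
  sdoy <- slot_mid_doy(slots)
  ndvi_t <- cfg$ndvi_base + cfg$ndvi_amp * season_shape(sdoy, cfg)
  lswi_shape <- season_shape(sdoy + cfg$lswi_lead_days, cfg)
  lswi_t <- cfg$lswi_base + cfg$lswi_amp * lswi_shape
  if (cfg$drought) {
    dry <- drought_windows(slots, cfg)
    lswi_t[dry] <- lswi_t[dry] - 0.35 * cfg$lswi_amp * lswi_shape[dry]
  }
  rho_nir <- cfg$rho_red_base * (1 + ndvi_t) / (1 - ndvi_t)
  rho_swir <- rho_nir * (1 - lswi_t) / (1 + lswi_t)
  list(ndvi = ndvi_t, lswi = lswi_t,
       evi = evi(rho_nir, cfg$rho_red_base, cfg$rho_blue_base),
       rho_nir = rho_nir, rho_swir = rho_swir)
}

#' Generate half-hourly drivers and 8-day reflectance for a scenario
#'
#' Deterministic driver fields: PAR is a clear-sky truncated diurnal arc
#' scaled by solar elevation; air temperature is a seasonal plus diurnal
#' sinusoid; soil temperature is a damped, lagged copy; VWC follows the
#' season shape (with a dry-spell dip under `drought`). Reflectance bands are
#' constructed so that NDVI and LSWI computed from them reproduce the
#' configured seasonal curves exactly. Optional QC corruption (seeded) marks
#' a fraction of composites bad and perturbs their reflectances.
#'
#' @param cfg [scenario_config()].
#' @return List with `flux` (half-hourly driver table: `timestamp`, `nee`
#'   all `NA`, `par`, `t_air`, `t_soil`, `vwc`, `precip`, `valid`) and
#'   `refl` (8-day reflectance table: `date`, bands, `qc_ok`).
#' @export
generate_drivers <- function(cfg) {
  stopifnot(inherits(cfg, "nee_scenario_config"))
  ts <- seq(as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(cfg$end, "23:30:00"), tz = "UTC"),
            by = 1800)
  doy <- as.integer(format(ts, "%j"))
  hour <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60

  par <- cfg$par_max * pmax(0, sin_elevation(doy, hour, cfg$latitude))

  # day-to-day synoptic anomalies: daily AR(1), damped + 5-day-smoothed in
  # the soil (this weather noise is what keeps window-mean air and soil
  # temperature from being perfectly collinear predictors)
  days_all <- unique(as.Date(format(ts, "%Y-%m-%d")))
  syn <- with_seed(cfg$seed + 4L, {
    e <- stats::rnorm(length(days_all), 0, cfg$t_air_synoptic_sd * sqrt(1 - 0.7^2))
    as.numeric(stats::filter(e, 0.7, method = "recursive"))
  })
  syn_soil <- as.numeric(stats::filter(syn, rep(1 / 5, 5), sides = 1))
  syn_soil[is.na(syn_soil)] <- syn[is.na(syn_soil)]
  di <- match(as.Date(format(ts, "%Y-%m-%d")), days_all)

  seas <- function(d, peak) cos(2 * pi * (d - peak) / 365)
  t_air <- cfg$t_air_mean + cfg$t_air_seas_amp * seas(doy, cfg$t_air_peak_doy) +
    cfg$t_air_diurnal_amp * cos(2 * pi * (hour - 15) / 24) + syn[di]
  t_soil <- cfg$t_air_mean + cfg$t_soil_offset +
    cfg$t_soil_damp_seas * cfg$t_air_seas_amp *
      seas(doy, cfg$t_air_peak_doy + cfg$t_soil_lag_days) +
    cfg$t_soil_damp_diurnal * cfg$t_air_diurnal_amp *
      cos(2 * pi * (hour - 17) / 24) +
    cfg$t_soil_damp_seas * syn_soil[di]

  # sparse monsoon-season precipitation events (seeded, independent stream);
  # a drought scenario suppresses event frequency in the dry spell
  days <- unique(as.Date(format(ts, "%Y-%m-%d")))
  day_doy <- as.integer(format(days, "%j"))
  rain_day <- with_seed(cfg$seed, {
    p_wet <- 0.45 * season_shape(day_doy, cfg)
    if (cfg$drought) {
      dry <- day_doy >= cfg$drought_start_doy & day_doy <= cfg$drought_end_doy
      p_wet[dry] <- 0.1 * p_wet[dry]
    }
    amt <- stats::rexp(length(days), rate = 1 / 6)
    ifelse(stats::runif(length(days)) < p_wet, amt, 0)
  })
  precip <- numeric(length(ts))
  at15 <- hour == 15  # book the daily total on one afternoon half-hour
  precip[at15] <- rain_day[match(as.Date(format(ts[at15], "%Y-%m-%d")), days)]

  # soil water: daily bucket filled by rain, first-order drainage toward the
  # dry baseline; episodic by construction, so VWC is correlated with but not
  # collinear to the smooth seasonal temperature/greenness curves
  vwc_max <- cfg$vwc_base + cfg$vwc_amp
  w <- numeric(length(days))
  level <- cfg$vwc_base + 0.25 * cfg$vwc_amp
  for (k in seq_along(days)) {
    level <- cfg$vwc_base + (level - cfg$vwc_base) * 0.96 + 0.012 * rain_day[k]
    w[k] <- min(level, vwc_max)
  }
  vwc <- w[match(as.Date(format(ts, "%Y-%m-%d")), days)]

  flux <- data.frame(timestamp = ts, nee = NA_real_, par = par,
                     t_air = t_air, t_soil = t_soil, vwc = vwc,
                     precip = precip, valid = TRUE)

  slots <- composite_slots(cfg$start, cfg$end)
  vi <- scenario_vi_curves(slots, cfg)
  refl <- data.frame(date = slots,
                     rho_blue = rep(cfg$rho_blue_base, length(slots)),
                     rho_red = rep(cfg$rho_red_base, length(slots)),
                     rho_nir = vi$rho_nir, rho_swir = vi$rho_swir,
                     qc_ok = TRUE)
  if (cfg$qc_fail_frac > 0) {
    bad <- with_seed(cfg$seed + 1L,
                     stats::runif(length(slots)) < cfg$qc_fail_frac)
    # cloud-like corruption: inflated visible reflectance, flagged bad
    refl$qc_ok[bad] <- FALSE
    refl$rho_blue[bad] <- pmin(1, refl$rho_blue[bad] + 0.3)
    refl$rho_red[bad] <- pmin(1, refl$rho_red[bad] + 0.3)
    refl$rho_nir[bad] <- pmin(1, refl$rho_nir[bad] + 0.2)
  }
  list(flux = flux, refl = refl)
}

#' Generate NEE observations and the window-level truth table
#'
#' Per 8-day window, true parameters are the configured linear maps of the
#' (uncorrupted) vegetation indices and window-mean soil temperature plus
#' Gaussian window-level noise, clipped to the inversion bounds. Half-hourly
#' NEE is `Reco - suppression * GPP + noise`; the suppression factor is 1
#' except in drought windows of a drought scenario (a deliberate model
#' mismatch for studying performance under dry conditions).
#'
#' @param drivers Output of [generate_drivers()].
#' @param cfg [scenario_config()].
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @return List: `flux` (complete half-hourly table with `nee` filled) and
#'   `truth` (per window: `window_start`, the generating indices and mean
#'   soil temperature, the four true parameters, `suppression`).
#' @export
generate_fluxes <- function(drivers, cfg, ca = 350) {
  stopifnot(inherits(cfg, "nee_scenario_config"))
  flux <- drivers$flux
  slots <- composite_slots(cfg$start, cfg$end)
  vi <- scenario_vi_curves(slots, cfg)
  ndvi_t <- vi$ndvi; lswi_t <- vi$lswi; evi_t <- vi$evi

  ws <- slot_start(flux$timestamp)
  t_soil_mean <- tapply(flux$t_soil, factor(ws, levels = as.character(slots)),
                        mean)
  opts <- inversion_options()
  clip <- function(x, pm) pmin(pmax(x, opts$lower[[pm]]), opts$upper[[pm]])
  truth <- with_seed(cfg$seed + 2L, {
    k <- length(slots)
    data.frame(
      window_start = slots, ndvi = ndvi_t, evi = evi_t, lswi = lswi_t,
      t_soil = as.numeric(t_soil_mean),
      alpha0 = clip(cfg$map_alpha0[[1]] + cfg$map_alpha0[[2]] * lswi_t +
                      stats::rnorm(k, 0, cfg$map_alpha0[[3]]), "alpha0"),
      gx = clip(cfg$map_gx[[1]] + cfg$map_gx[[2]] * evi_t +
                  stats::rnorm(k, 0, cfg$map_gx[[3]]), "gx"),
      b0 = clip(cfg$map_b0[[1]] + cfg$map_b0[[2]] * evi_t +
                  stats::rnorm(k, 0, cfg$map_b0[[3]]), "b0"),
      b = clip(cfg$map_b[[1]] + cfg$map_b[[2]] * as.numeric(t_soil_mean) +
                 stats::rnorm(k, 0, cfg$map_b[[3]]), "b"))
  })
  truth$suppression <- ifelse(drought_windows(slots, cfg),
                              cfg$gpp_suppression, 1)

  i <- match(ws, slots)
  g <- gpp(flux$par, flux$t_air, truth$alpha0[i], truth$gx[i], ca)
  r <- reco(flux$t_soil, truth$b0[i], truth$b[i])
  noise <- if (cfg$nee_noise_sd > 0) {
    with_seed(cfg$seed + 3L, stats::rnorm(nrow(flux), 0, cfg$nee_noise_sd))
  } else 0
  flux$nee <- r - truth$suppression[i] * g + noise
  list(flux = flux, truth = truth)
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: [generate_drivers()] then [generate_fluxes()].
#'
#' @inheritParams generate_fluxes
#' @return List: `flux`, `refl`, `truth`.
#' @export
generate_scenario <- function(cfg = scenario_config(), ca = 350) {
  drv <- generate_drivers(cfg)
  fl <- generate_fluxes(drv, cfg, ca)
  list(flux = fl$flux, refl = drv$refl, truth = fl$truth)
}
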