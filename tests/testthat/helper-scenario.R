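# Shared fixture builders: everything is generated in code at test time.

# one 8-day mid-season window of drivers with NEE from known parameters
make_window_flux <- function(alpha0 = 0.025, gx = 0.02, b0 = 1, b = 0.1,
                             noise_sd = 0, seed = 1,
                             start = "2007-07-12", end = "2007-07-19") {
  cfg <- scenario_config(start = start, end = end, nee_noise_sd = 0)
  fl <- generate_drivers(cfg)$flux
  fl$nee <- nee(fl$par, fl$t_air, fl$t_soil, alpha0, gx, b0, b)
  if (noise_sd > 0) {
    set.seed(seed)
    fl$nee <- fl$nee + rnorm(nrow(fl), 0, noise_sd)
  }
  fl
}

# 8-day predictor table (VIs + window-mean environment) for calibration
make_predictor_table <- function(indices, flux) {
  vi <- stats::setNames(indices[, c("date", "ndvi", "evi", "lswi")],
                        c("window_start", "ndvi", "evi", "lswi"))
  merge(vi, window_environment(flux), by = "window_start")
}

# small reflectance table on the 8-day grid with given NDVI targets
make_refl <- function(ndvi_target, start = "2007-04-23",
                      red = 0.1, blue = 0.05, swir = 0.15) {
  n <- length(ndvi_target)
  dates <- composite_slots(start, as.Date(start) + 8 * (n - 1))
  data.frame(date = dates, rho_blue = blue, rho_red = red,
             rho_nir = red * (1 + ndvi_target) / (1 - ndvi_target),
             rho_swir = swir, qc_ok = TRUE)
}
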