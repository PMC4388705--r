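# Forward biophysical kernel: GPP light response, Van't Hoff respiration, NEE.
# All functions are vectorized over their driver arguments and recycle scalar
# parameters; units follow the flux-community convention
# (micromol CO2 m^-2 s^-1 for fluxes, micromol mol^-1 for CO2 concentrations).

#' Temperature-dependent CO2 compensation point
#'
#' Apparent CO2 concentration in the chloroplast at the photosynthetic
#' compensation point, as a quadratic in absolute temperature:
#' \deqn{\tau = 42.7 + 1.68\,(T - 298) + 0.0012\,(T - 298)^2}
#' with `T` in Kelvin. Air temperature is supplied in degrees Celsius and
#' converted internally (`T = t_air + 273.15`). The quadratic is a local
#' approximation, so the result is clipped to `[0, 0.99 * ca]` to keep the
#' downstream light-response terms well defined at extreme temperatures.
#'
#' @param t_air Air temperature, degrees C. Values outside -60..60 C trigger a
#'   warning (the approximation is not meant for them) but are still evaluated.
#' @param ca Ambient CO2 concentration, micromol mol^-1 (default 350). Used
#'   only as the upper clipping bound.
#' @return CO2 compensation point, micromol mol^-1 (same length as `t_air`).
#' @examples
#' compensation_point(24.85) # T = 298 K -> 42.7
#' compensation_point(c(0, 10, 25))
#' @export
compensation_point <- function(t_air, ca = 350) {
  stopifnot(is.numeric(t_air), is.numeric(ca), all(ca > 0))
  if (any(t_air < -60 | t_air > 60, na.rm = TRUE)) {
    warning("air temperature outside the plausible -60..60 C range; ",
            "the compensation-point quadratic is a local approximation",
            call. = FALSE)
  }
  d <- (t_air + 273.15) - 298
  tau <- 42.7 + 1.68 * d + 0.0012 * d^2
  pmin(pmax(tau, 0), 0.99 * ca)
}

#' Apparent quantum use efficiency at ambient CO2
#'
#' Scales the apparent maximum quantum use efficiency `alpha0` by the
#' CO2-availability factor `(Ca - tau) / (Ca + 2 tau)` (Goudriaan form), giving
#' the initial slope of the canopy light-response curve at the current
#' compensation point.
#'
#' @param alpha0 Apparent maximum quantum use efficiency,
#'   micromol CO2 micromol^-1 PAR; must be >= 0.
#' @param tau CO2 compensation point, micromol mol^-1 (see
#'   [compensation_point()]); must satisfy `0 <= tau < ca`.
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @return Apparent quantum use efficiency alpha, same units as `alpha0`;
#'   bounded by `0 <= alpha <= alpha0`.
#' @export
apparent_quantum_efficiency <- function(alpha0, tau, ca = 350) {
  stopifnot(all(alpha0 >= 0, na.rm = TRUE))
  check_tau(tau, ca)
  alpha0 * (ca - tau) / (ca + 2 * tau)
}

#' Apparent maximum photosynthetic rate
#'
#' The light-saturated asymptote of the canopy light-response curve,
#' proportional to the CO2 draw-down `(Ca - tau)` through the carboxylation
#' conductance `gx`.
#'
#' @param gx Carboxylation conductance (proportionality between the maximum
#'   assimilation rate and `Ca - tau`); must be >= 0.
#' @param tau CO2 compensation point, micromol mol^-1; `0 <= tau < ca`.
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @return beta, micromol CO2 m^-2 s^-1.
#' @export
apparent_max_photosynthesis <- function(gx, tau, ca = 350) {
  stopifnot(all(gx >= 0, na.rm = TRUE))
  check_tau(tau, ca)
  (ca - tau) * gx
}

check_tau <- function(tau, ca) {
  if (any(tau >= ca, na.rm = TRUE) || any(tau < 0, na.rm = TRUE)) {
    stop_neeflux("invalid_state",
                 "compensation point tau must satisfy 0 <= tau < ca")
  }
  invisible(tau)
}

#' Gross primary productivity: rectangular-hyperbola light response
#'
#' \deqn{GPP = \alpha \beta PAR / (\beta + \alpha PAR)}
#' where alpha and beta are derived from `alpha0`, `gx` and the
#' temperature-dependent compensation point ([apparent_quantum_efficiency()],
#' [apparent_max_photosynthesis()]). GPP is zero in the dark, increases
#' monotonically with PAR, and saturates below beta; at `PAR = beta / alpha` it
#' equals `beta / 2` (half saturation).
#'
#' @param par Photosynthetically active radiation, micromol m^-2 s^-1; >= 0.
#' @param t_air Air temperature, degrees C (drives the compensation point).
#' @param alpha0 Apparent maximum quantum use efficiency.
#' @param gx Carboxylation conductance.
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @return GPP, micromol CO2 m^-2 s^-1 (>= 0). Degenerate parameter
#'   combinations with `beta + alpha * PAR = 0` return 0.
#' @export
gpp <- function(par, t_air, alpha0, gx, ca = 350) {
  stopifnot(all(par >= 0, na.rm = TRUE))
  tau <- compensation_point(t_air, ca)
  a <- apparent_quantum_efficiency(alpha0, tau, ca)
  b <- apparent_max_photosynthesis(gx, tau, ca)
  denom <- b + a * par
  out <- a * b * par
  nz <- !is.na(denom) & denom > 0
  out[nz] <- out[nz] / denom[nz]
  out[!nz & !is.na(denom)] <- 0
  out
}

#' Ecosystem respiration: Van't Hoff exponential
#'
#' \deqn{R_{eco} = b_0 e^{b\,T_{soil}}}
#' `b0` is the respiration rate at the 0 degrees C reference; `exp(10 b)` is
#' the Q10 of the response.
#'
#' @param t_soil Soil temperature at 5 cm depth, degrees C.
#' @param b0 Respiration rate at 0 C, micromol CO2 m^-2 s^-1; >= 0.
#' @param b Temperature-sensitivity coefficient, per degree C.
#' @return Ecosystem respiration, micromol CO2 m^-2 s^-1.
#' @export
reco <- function(t_soil, b0, b) {
  stopifnot(all(b0 >= 0, na.rm = TRUE))
  b0 * exp(b * t_soil)
}

#' Net ecosystem exchange (micrometeorological sign convention)
#'
#' `NEE = Reco - GPP`: negative values are net ecosystem uptake, positive
#' values a net source, matching the convention of eddy-covariance NEE series.
#'
#' @inheritParams gpp
#' @inheritParams reco
#' @return NEE, micromol CO2 m^-2 s^-1; negative = uptake.
#' @seealso [nee_composite()] for the equivalent single-expression form with
#'   the opposite (uptake-positive) orientation.
#' @export
nee <- function(par, t_air, t_soil, alpha0, gx, b0, b, ca = 350) {
  reco(t_soil, b0, b) - gpp(par, t_air, alpha0, gx, ca)
}

#' Composite NEE expression (uptake-positive orientation)
#'
#' Single-expression form of the model,
#' \deqn{(C_a-\tau)\,\alpha_0 g_x PAR / ((C_a+2\tau) g_x + \alpha_0 PAR)
#'       - b_0 e^{b T_{soil}},}
#' algebraically equal to `GPP - Reco`, i.e. the negation of [nee()]. Kept as
#' an independent evaluation route for cross-checking the factored kernel.
#'
#' @inheritParams nee
#' @return `GPP - Reco`, micromol CO2 m^-2 s^-1; positive = uptake.
#' @export
nee_composite <- function(par, t_air, t_soil, alpha0, gx, b0, b, ca = 350) {
  stopifnot(all(par >= 0, na.rm = TRUE))
  tau <- compensation_point(t_air, ca)
  check_tau(tau, ca)
  denom <- (ca + 2 * tau) * gx + par * alpha0
  g <- (ca - tau) * alpha0 * gx * par
  nz <- !is.na(denom) & denom > 0
  g[nz] <- g[nz] / denom[nz]
  g[!nz & !is.na(denom)] <- 0
  g - reco(t_soil, b0, b)
}
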