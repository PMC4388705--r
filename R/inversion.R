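# Per-window least-squares inversion of the four model parameters
# (alpha0, gx, b0, b) from half-hourly NEE, with linearized standard errors.

PARAM_NAMES <- c("alpha0", "gx", "b0", "b")

#' Inversion options
#'
#' Bounds, starting values and data requirements for the windowed
#' least-squares inversion. The bounds encode physical plausibility: 0.125 is
#' the theoretical ceiling of quantum use efficiency (1/8 CO2 per photon), and
#' the respiration bounds keep the exponential term from diverging.
#'
#' @param lower,upper Named numeric bounds for `alpha0`, `gx`, `b0`, `b`.
#' @param start Default starting point, used when no previous-window estimate
#'   is available.
#' @param min_obs Minimum number of valid half-hours per 8-day window
#'   (default 96, i.e. 25% of the 384 possible).
#' @param n_restarts Number of additional deterministic starts tried when the
#'   first fit fails to converge or lands on a bound.
#' @return A list of class `nee_inversion_options`.
#' @export
inversion_options <- function(lower = c(alpha0 = 0, gx = 0, b0 = 0, b = 0),
                              upper = c(alpha0 = 0.125, gx = 1, b0 = 20, b = 0.5),
                              start = c(alpha0 = 0.02, gx = 0.01, b0 = 1, b = 0.1),
                              min_obs = 96,
                              n_restarts = 3) {
  for (v in list(lower, upper, start)) {
    stopifnot(is.numeric(v), setequal(names(v), PARAM_NAMES))
  }
  lower <- lower[PARAM_NAMES]; upper <- upper[PARAM_NAMES]
  start <- pmin(pmax(start[PARAM_NAMES], lower), upper)
  stopifnot(all(lower <= upper), min_obs >= 5)
  structure(list(lower = lower, upper = upper, start = start,
                 min_obs = min_obs, n_restarts = n_restarts),
            class = "nee_inversion_options")
}

# rows of `flux` usable for fitting
valid_fit_rows <- function(flux) {
  v <- if ("valid" %in% names(flux)) flux$valid else rep(TRUE, nrow(flux))
  v & stats::complete.cases(flux[, c("nee", "par", "t_air", "t_soil")])
}

# residual vector model - obs for free params `p` (fixed ones merged in)
nee_residuals <- function(p, fixed, dat, ca) {
  full <- c(p, fixed)[PARAM_NAMES]
  nee(dat$par, dat$t_air, dat$t_soil,
      full[["alpha0"]], full[["gx"]], full[["b0"]], full[["b"]], ca) - dat$nee
}

# analytic Jacobian of the residual vector (= of modeled NEE) wrt free params
nee_jacobian <- function(p, fixed, dat, ca) {
  full <- c(p, fixed)[PARAM_NAMES]
  tau <- compensation_point(dat$t_air, ca)
  ratio <- (ca - tau) / (ca + 2 * tau)
  a <- full[["alpha0"]] * ratio          # apparent quantum efficiency
  bmax <- (ca - tau) * full[["gx"]]      # apparent maximum photosynthesis
  denom <- bmax + a * dat$par
  inv2 <- ifelse(denom > 0, 1 / denom^2, 0)
  dgpp_da  <- bmax^2 * dat$par * inv2
  dgpp_db  <- a^2 * dat$par^2 * inv2
  expb <- exp(full[["b"]] * dat$t_soil)
  cols <- list(
    alpha0 = -dgpp_da * ratio,
    gx     = -dgpp_db * (ca - tau),
    b0     = expb,
    b      = full[["b0"]] * dat$t_soil * expb)
  J <- do.call(cbind, cols[names(p)])
  colnames(J) <- names(p)
  J
}

# linearized covariance diag: rss/(n-k) * diag((J'J)^-1) via eigendecomposition,
# returning Inf variance along (numerically) null directions
linearized_se <- function(J, rss) {
  n <- nrow(J); k <- ncol(J)
  if (n <= k) return(rep(Inf, k))
  sigma2 <- rss / (n - k)
  A <- crossprod(J)
  e <- eigen(A, symmetric = TRUE)
  tol <- max(e$values, 0) * 1e-10
  inv_diag <- vapply(seq_len(k), function(j) {
    contrib <- e$vectors[j, ]^2 / e$values
    contrib[e$values <= tol] <- Inf
    sum(contrib)
  }, numeric(1))
  se <- sqrt(sigma2 * inv_diag)
  se[is.infinite(inv_diag)] <- Inf # unidentified stays Inf even at rss = 0
  se
}

# deterministic alternative starts: bound midpoint and scaled variants
candidate_starts <- function(start, lower, upper, n) {
  mids <- (lower + pmin(upper, 10 * pmax(start, lower + 1e-6))) / 2
  alts <- list(mids,
               pmin(pmax(start * 0.25, lower), upper),
               pmin(pmax(start * 4, lower), upper),
               pmin(pmax((lower + upper) / 2, lower), upper))
  alts[seq_len(min(n, length(alts)))]
}

fit_window_ls <- function(dat, ca, opts, fixed = numeric(0), start = NULL) {
  free <- setdiff(PARAM_NAMES, names(fixed))
  if (is.null(start)) start <- opts$start
  start <- pmin(pmax(start[free], opts$lower[free]), opts$upper[free])
  obj <- function(p) {
    names(p) <- free
    sum(nee_residuals(p, fixed, dat, ca)^2)
  }
  grad <- function(p) {
    names(p) <- free
    r <- nee_residuals(p, fixed, dat, ca)
    drop(2 * crossprod(nee_jacobian(p, fixed, dat, ca), r))
  }
  run <- function(s) {
    suppressWarnings(stats::nlminb(
      s, obj, gradient = grad,
      lower = opts$lower[free], upper = opts$upper[free],
      control = list(eval.max = 2000, iter.max = 1000,
                     rel.tol = 1e-15, x.tol = 1e-14)))
  }
  # multi-start: the exponential respiration term has local minima, so the
  # window start (previous estimate) is always backed by deterministic
  # alternates; the best objective wins
  best <- run(start)
  for (s in candidate_starts(opts$start[free], opts$lower[free],
                             opts$upper[free], opts$n_restarts)) {
    cand <- run(s)
    if (cand$objective < best$objective) best <- cand
  }
  p <- best$par; names(p) <- free
  rss <- best$objective
  J <- nee_jacobian(p, fixed, dat, ca)
  se <- linearized_se(J, rss)
  names(se) <- free
  full <- c(p, fixed)[PARAM_NAMES]
  se_full <- c(se, stats::setNames(rep(0, length(fixed)), names(fixed)))[PARAM_NAMES]
  # nlminb codes 0 ("*-convergence") and the flat-objective messages indicate
  # a usable optimum; identifiability additionally requires finite SEs
  ok_msg <- best$convergence == 0 ||
    grepl("relative convergence|X-convergence|singular convergence",
          best$message %||% "")
  list(par = full, se = se_full, rss = rss,
       converged = ok_msg && all(is.finite(se)))
}

parameter_row <- function(window_start, par, se, n_obs, rss, converged) {
  data.frame(window_start = as.Date(window_start),
             alpha0 = par[["alpha0"]], se_alpha0 = se[["alpha0"]],
             gx = par[["gx"]], se_gx = se[["gx"]],
             b0 = par[["b0"]], se_b0 = se[["b0"]],
             b = par[["b"]], se_b = se[["b"]],
             n_obs = n_obs, rss = rss, converged = converged)
}

empty_parameter_row <- function(window_start, n_obs) {
  na4 <- stats::setNames(rep(NA_real_, 4), PARAM_NAMES)
  parameter_row(window_start, na4, na4, n_obs, NA_real_, FALSE)
}

#' Invert the four model parameters from one 8-day window of NEE
#'
#' Fits `alpha0`, `gx`, `b0` and `b` by bounded nonlinear least squares on all
#' valid half-hourly NEE observations in the window, minimising
#' `sum((nee_model - nee_obs)^2)` with `nee_model = Reco - GPP` (negative =
#' uptake, matching the stored observations). Standard errors come from the
#' linearized covariance `rss/(n-k) * diag((J'J)^-1)` at the optimum; if the
#' window carries no information on a parameter (e.g. no daytime data for the
#' photosynthesis pair) the corresponding SE is infinite and the fit is
#' flagged unconverged.
#'
#' @param flux Data frame of half-hourly records with columns `timestamp`
#'   (POSIXct), `nee`, `par`, `t_air`, `t_soil` and optionally logical
#'   `valid`; all rows must fall in one 8-day slot.
#' @param ca Ambient CO2 concentration, micromol mol^-1.
#' @param opts [inversion_options()].
#' @param start Optional named starting values (e.g. the previous window's
#'   estimate).
#' @param fix Optional named numeric holding `b` and/or `b0` fixed (the
#'   respiration pair is mutually near-collinear; see
#'   [invert_window_fixed()]). Fixed parameters get SE 0.
#' @return One-row data frame: `window_start`, the four estimates with
#'   standard errors (`se_*`), `n_obs`, `rss`, `converged`.
#' @export
invert_window <- function(flux, ca = 350, opts = inversion_options(),
                          start = NULL, fix = numeric(0)) {
  if (length(fix)) {
    stopifnot(all(names(fix) %in% c("b", "b0")))
  }
  ws <- unique(slot_start(flux$timestamp))
  if (length(ws) != 1) {
    stop_neeflux("invalid_state",
                 "records span more than one 8-day slot; use invert_series()")
  }
  keep <- valid_fit_rows(flux)
  dat <- flux[keep, , drop = FALSE]
  if (nrow(dat) < opts$min_obs) {
    stop_neeflux("insufficient_data",
                 sprintf("window %s has %d valid records (< min_obs = %d)",
                         format(ws), nrow(dat), opts$min_obs))
  }
  fit <- fit_window_ls(dat, ca, opts, fixed = fix, start = start)
  parameter_row(ws, fit$par, fit$se, nrow(dat), fit$rss, fit$converged)
}

#' Three-parameter inversion with one respiration parameter fixed
#'
#' The respiration pair (`b0`, `b`) is strongly negatively correlated within a
#' window (a given respiration level can be matched by trading base rate
#' against temperature sensitivity). Holding one of them at an externally
#' supplied value and inverting the other stabilises the fit.
#'
#' @inheritParams invert_window
#' @param fix Named numeric of length 1: `c(b = value)` or `c(b0 = value)`.
#' @return As [invert_window()]; the fixed parameter is reported with SE 0.
#' @export
invert_window_fixed <- function(flux, fix, ca = 350,
                                opts = inversion_options(), start = NULL) {
  stopifnot(length(fix) >= 1, all(names(fix) %in% c("b", "b0")))
  invert_window(flux, ca = ca, opts = opts, start = start, fix = fix)
}

#' Invert parameters for every 8-day window of a flux series
#'
#' Partitions the record on the DOY 1, 9, ..., 361 slot grid and runs
#' [invert_window()] per slot. Each converged window's estimate seeds the next
#' window's optimisation (the seasonal trajectories are smooth). Windows with
#' insufficient data or failed fits yield flagged rows (`converged = FALSE`,
#' `NA` estimates where nothing could be fit); they never abort the series.
#'
#' @inheritParams invert_window
#' @param flux Data frame spanning one or more 8-day slots.
#' @return Data frame with one row per slot in the covered period (columns as
#'   [invert_window()]).
#' @export
invert_series <- function(flux, ca = 350, opts = inversion_options(),
                          fix = numeric(0)) {
  if (nrow(flux) == 0) stop_neeflux("empty_input", "no flux records supplied")
  ws <- slot_start(flux$timestamp)
  slots <- composite_slots(min(ws), max(ws))
  prev <- NULL
  rows <- vector("list", length(slots))
  for (k in seq_along(slots)) {
    sel <- ws == slots[k]
    n_valid <- sum(valid_fit_rows(flux[sel, , drop = FALSE]))
    rows[[k]] <- tryCatch(
      invert_window(flux[sel, , drop = FALSE], ca = ca, opts = opts,
                    start = prev, fix = fix),
      neeflux_error = function(e) empty_parameter_row(slots[k], n_valid)
    )
    if (isTRUE(rows[[k]]$converged)) {
      prev <- stats::setNames(
        as.numeric(rows[[k]][, PARAM_NAMES]), PARAM_NAMES)
    }
  }
  do.call(rbind, rows)
}
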