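# Windowed least-squares parameter inversion.

test_that("8-day slot arithmetic follows the DOY 1, 9, ..., 361 grid", {
  expect_equal(slot_start(as.Date("2007-01-01")), as.Date("2007-01-01"))
  expect_equal(slot_start(as.Date("2007-01-08")), as.Date("2007-01-01"))
  expect_equal(slot_start(as.Date("2007-01-09")), as.Date("2007-01-09"))
  # the last slot absorbs the year's trailing days (incl. leap years)
  expect_equal(slot_start(as.Date("2007-12-31")),
               as.Date("2007-01-01") + 360)
  expect_equal(slot_start(as.Date("2008-12-31")),
               as.Date("2008-01-01") + 360)
  expect_equal(length(composite_slots("2007-01-01", "2007-12-31")), 46)
  expect_error(composite_slots("2007-02-01", "2007-01-01"),
               class = "neeflux_invalid_config")
})

test_that("noiseless windows recover the generating parameters", {
  truth <- c(alpha0 = 0.025, gx = 0.02, b0 = 1.0, b = 0.10)
  fl <- make_window_flux(truth[1], truth[2], truth[3], truth[4])
  ps <- invert_window(fl)
  est <- as.numeric(ps[, c("alpha0", "gx", "b0", "b")])
  expect_lt(max(abs(est - truth) / truth), 1e-4)
  expect_true(ps$converged)
  expect_equal(ps$n_obs, 384)
  expect_lt(ps$rss, 1e-10)

  # property: 20 random parameter draws within bounds, relative error < 1e-3
  cfg <- scenario_config(start = "2007-07-12", end = "2007-07-19",
                         nee_noise_sd = 0)
  drv <- generate_drivers(cfg)$flux
  set.seed(42)
  for (i in 1:20) {
    tr <- c(alpha0 = runif(1, 0.005, 0.05), gx = runif(1, 0.005, 0.05),
            b0 = runif(1, 0.2, 4), b = runif(1, 0.03, 0.25))
    drv$nee <- nee(drv$par, drv$t_air, drv$t_soil, tr[1], tr[2], tr[3], tr[4])
    est <- as.numeric(invert_window(drv)[, c("alpha0", "gx", "b0", "b")])
    expect_lt(max(abs(est - tr) / tr), 1e-3)
  }
})

test_that("noisy replicates: small bias, honest SEs, b-b0 anti-correlation", {
  truth <- c(alpha0 = 0.025, gx = 0.02, b0 = 1.0, b = 0.10)
  fl <- make_window_flux(truth[1], truth[2], truth[3], truth[4])
  clean <- fl$nee
  n_rep <- 25
  est <- se <- matrix(NA_real_, n_rep, 4)
  set.seed(202)
  for (r in seq_len(n_rep)) {
    fl$nee <- clean + rnorm(nrow(fl), 0, 0.5)
    ps <- invert_window(fl)
    est[r, ] <- as.numeric(ps[, c("alpha0", "gx", "b0", "b")])
    se[r, ] <- as.numeric(ps[, c("se_alpha0", "se_gx", "se_b0", "se_b")])
    # optimizer sanity: objective at optimum <= objective at truth
    rss_truth <- sum((nee(fl$par, fl$t_air, fl$t_soil, truth[1], truth[2],
                          truth[3], truth[4]) - fl$nee)^2)
    expect_lte(ps$rss, rss_truth + 1e-8)
  }
  expect_lt(max(abs(colMeans(est) / truth - 1)), 0.1)
  ratio <- colMeans(se) / apply(est, 2, sd)
  expect_true(all(ratio > 0.5 & ratio < 2))
  expect_lt(cor(est[, 3], est[, 4]), 0) # base rate trades against sensitivity
})

test_that("a window with no daytime data leaves photosynthesis unidentified", {
  fl <- make_window_flux(0.025, 0.02, 1.0, 0.10)
  fl$par <- 0
  fl$nee <- nee(fl$par, fl$t_air, fl$t_soil, 0.025, 0.02, 1.0, 0.10)
  ps <- invert_window(fl)
  expect_false(ps$converged)
  expect_true(is.infinite(ps$se_alpha0) || is.infinite(ps$se_gx))
  # the respiration pair is still recovered from the night signal
  expect_lt(abs(ps$b0 - 1.0) / 1.0, 1e-3)
  expect_lt(abs(ps$b - 0.10) / 0.10, 1e-3)
})

test_that("insufficient data and multi-slot input are signalled", {
  fl <- make_window_flux()
  expect_error(invert_window(fl[1:50, ]), class = "neeflux_insufficient_data")
  fl$valid[1:320] <- FALSE
  expect_error(invert_window(fl), class = "neeflux_insufficient_data")
  two <- make_window_flux(start = "2007-07-12", end = "2007-07-27")
  expect_error(invert_window(two), class = "neeflux_invalid_state")
})

test_that("fixed-parameter fits behave as constrained versions of the free fit", {
  truth <- c(alpha0 = 0.025, gx = 0.02, b0 = 1.0, b = 0.10)
  fl <- make_window_flux(truth[1], truth[2], truth[3], truth[4])

  # fixing b at truth on noiseless data recovers b0 to 1e-4
  ps_b <- invert_window_fixed(fl, fix = c(b = 0.10))
  expect_equal(ps_b$b, 0.10)
  expect_equal(ps_b$se_b, 0)
  expect_lt(abs(ps_b$b0 - 1.0), 1e-4)

  ps_b0 <- invert_window_fixed(fl, fix = c(b0 = 1.0))
  expect_lt(abs(ps_b0$b - 0.10), 1e-4)

  # fixing at the free-fit optimum reproduces the free-fit objective
  free <- invert_window(fl)
  ps_at <- invert_window_fixed(fl, fix = c(b = free$b))
  expect_equal(ps_at$rss, free$rss, tolerance = 1e-6)

  # on noisy data, fixing b0 at truth shrinks the variance of b estimates
  clean <- fl$nee
  set.seed(303)
  b_free <- b_fix <- numeric(12)
  for (r in 1:12) {
    fl$nee <- clean + rnorm(nrow(fl), 0, 0.5)
    b_free[r] <- invert_window(fl)$b
    b_fix[r] <- invert_window_fixed(fl, fix = c(b0 = 1.0))$b
  }
  expect_lt(var(b_fix), var(b_free))
})

test_that("series inversion tracks a drifting seasonal truth", {
  # low observation noise: this checks trajectory tracking, not noise
  # robustness (the Monte-Carlo test above covers sigma = 0.5)
  cfg <- scenario_config(start = "2007-04-01", end = "2007-10-31",
                         seed = 9, nee_noise_sd = 0.1)
  sc <- generate_scenario(cfg)
  ps <- invert_series(sc$flux)
  slots <- composite_slots("2007-04-01", "2007-10-31")
  expect_equal(ps$window_start, slots)
  # record conservation over windows
  expect_equal(sum(ps$n_obs), sum(sc$flux$valid))
  m <- merge(ps[ps$converged, ], sc$truth, by = "window_start",
             suffixes = c("", ".true"))
  expect_gt(nrow(m), 20)
  for (p in c("alpha0", "gx", "b0", "b")) {
    expect_gt(cor(m[[p]], m[[paste0(p, ".true")]]), 0.95)
  }
})

test_that("an empty slot mid-series is flagged without hurting neighbours", {
  fl <- make_window_flux(start = "2007-07-04", end = "2007-07-27") # 3 slots
  truth <- c(0.025, 0.02, 1.0, 0.10)
  fl$nee <- nee(fl$par, fl$t_air, fl$t_soil,
                truth[1], truth[2], truth[3], truth[4])
  mid <- slot_start(fl$timestamp) == as.Date("2007-07-12")
  fl$valid[mid] <- FALSE
  ps <- invert_series(fl)
  expect_equal(nrow(ps), 3)
  expect_false(ps$converged[2])
  expect_true(is.na(ps$alpha0[2]))
  expect_true(all(ps$converged[c(1, 3)]))
  expect_lt(abs(ps$alpha0[1] - truth[1]) / truth[1], 1e-3)
})
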