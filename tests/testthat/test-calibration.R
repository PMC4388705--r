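# Parameter-predictor regression, predictor selection, parameter prediction.

# a minimal converged parameter table over n windows
fake_params <- function(n, alpha0, gx = 0.02, b0 = 1, b = 0.1,
                        start = "2007-01-01") {
  slots <- composite_slots(start, as.Date(start) + 9 * n)[seq_len(n)]
  data.frame(window_start = slots, alpha0 = alpha0, se_alpha0 = 0,
             gx = gx, se_gx = 0, b0 = b0, se_b0 = 0, b = b, se_b = 0,
             n_obs = 384, rss = 0, converged = TRUE)
}

test_that("a perfectly proportional predictor gives r2 = 1 and exact slope", {
  n <- 20
  x <- seq(0.1, 0.5, length.out = n)
  params <- fake_params(n, alpha0 = 0.05 * x)
  pred <- data.frame(window_start = params$window_start, lswi = x)
  cand <- fit_candidates(params, pred)
  row <- cand[cand$parameter == "alpha0" & cand$predictor == "lswi", ]
  expect_equal(row$r2, 1)
  expect_equal(row$slope, 0.05, tolerance = 1e-10)
  expect_equal(row$intercept, 0, tolerance = 1e-12)
  expect_equal(row$n, n)
})

test_that("r2 is invariant to affine rescaling of the predictor", {
  set.seed(5)
  n <- 30
  x <- runif(n)
  params <- fake_params(n, alpha0 = 0.01 + 0.04 * x + rnorm(n, 0, 0.003))
  r2_of <- function(z) {
    pred <- data.frame(window_start = params$window_start, lswi = z)
    cand <- fit_candidates(params, pred)
    cand$r2[cand$parameter == "alpha0" & cand$predictor == "lswi"]
  }
  expect_equal(r2_of(x), r2_of(10 * x - 3), tolerance = 1e-12)
})

test_that("independent predictors yield null-distributed p-values", {
  set.seed(99)
  n <- 100
  reps <- 300
  pvals <- r2s <- numeric(reps)
  for (i in seq_len(reps)) {
    y <- rnorm(n)
    x <- rnorm(n)
    fit <- summary(lm(y ~ x))
    pvals[i] <- fit$coefficients[2, 4]
    r2s[i] <- fit$r.squared
  }
  # the package's regression must agree with this null behaviour
  params <- fake_params(n, alpha0 = rnorm(n, 0.02, 0.005))
  set.seed(100)
  pred <- data.frame(window_start = params$window_start, lswi = rnorm(n))
  cand <- fit_candidates(params, pred)
  expect_lt(cand$r2[cand$parameter == "alpha0" & cand$predictor == "lswi"],
            quantile(r2s, 0.999))
  # p-values under the null are roughly uniform
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("generative linear map is recovered within 2 SE", {
  set.seed(21)
  n <- 46
  lswi_x <- 0.25 * exp(-((seq_len(n) - 25) / 10)^2) - 0.05
  truth_slope <- 0.08; truth_int <- 0.006
  a0 <- truth_int + truth_slope * lswi_x + rnorm(n, 0, 0.001)
  params <- fake_params(n, alpha0 = pmax(a0, 0))
  pred <- data.frame(window_start = params$window_start, lswi = lswi_x)
  cand <- fit_candidates(params, pred)
  row <- cand[cand$parameter == "alpha0" & cand$predictor == "lswi", ]
  fit <- lm(params$alpha0 ~ lswi_x)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(row$slope - truth_slope), 2 * se[2])
  expect_lt(abs(row$intercept - truth_int), 2 * se[1])
})

test_that("selection picks max-r2 significant candidate, else falls back", {
  cand <- data.frame(
    parameter = "alpha0",
    predictor = c("ndvi", "evi", "lswi"),
    slope = 1, intercept = 0,
    r2 = c(0.5, 0.7, 0.3), p = c(0.001, 0.001, 0.001), n = 30)
  params <- fake_params(10, alpha0 = 0.02)
  suite <- select_suite(cand, params,
                        allowed = list(alpha0 = c("ndvi", "evi", "lswi"),
                                       gx = "evi", b0 = "evi", b = "t_soil"))
  expect_equal(suite$functions$alpha0$predictor, "evi")
  expect_false(suite$functions$alpha0$fallback)

  # nothing significant -> constant fallback at the median inverted value
  cand$p <- 0.5
  suite2 <- select_suite(cand, params)
  expect_true(suite2$functions$alpha0$fallback)
  expect_equal(suite2$functions$alpha0$intercept, 0.02)
  expect_equal(suite2$functions$alpha0$slope, 0)
  # selected r2 >= every other significant admissible candidate
  cand3 <- suite$candidates
  sel <- suite$functions$alpha0
  other <- cand3[cand3$parameter == "alpha0" & cand3$p < 0.05, ]
  expect_true(all(sel$r2 >= other$r2))
})

test_that("prediction applies the linear maps with bound clipping", {
  n <- 10
  params <- fake_params(n, alpha0 = 0.02)
  pred <- data.frame(window_start = params$window_start,
                     lswi = seq(-0.4, 0.6, length.out = n),
                     evi = seq(0.05, 0.3, length.out = n),
                     t_soil = seq(-5, 10, length.out = n))
  cand <- data.frame(
    parameter = c("alpha0", "gx", "b0", "b"),
    predictor = c("lswi", "evi", "evi", "t_soil"),
    slope = c(0.08, 0.06, 5, -0.004),
    intercept = c(0.006, 0.004, 0.3, 0.135),
    r2 = 0.9, p = 1e-6, n = n)
  suite <- select_suite(cand, params)
  out <- predict_parameters(suite, pred)
  expect_equal(out$gx, 0.004 + 0.06 * pred$evi)
  expect_equal(out$b, 0.135 - 0.004 * pred$t_soil)
  # the most negative LSWI would give negative alpha0: clipped at 0
  expect_equal(out$alpha0[1], 0)
  expect_true(all(out$alpha0 >= 0))

  # zero slopes give constant parameters equal to the intercepts
  cand0 <- cand; cand0$slope <- 0
  out0 <- predict_parameters(select_suite(cand0, params), pred)
  expect_equal(unique(out0$b0), 0.3)

  # round trip: refitting on predicted values returns identical coefficients
  params2 <- fake_params(n, alpha0 = out$gx) # any column; use gx map
  params2$gx <- out$gx
  cand2 <- fit_candidates(params2, pred)
  row <- cand2[cand2$parameter == "gx" & cand2$predictor == "evi", ]
  expect_equal(row$slope, 0.06, tolerance = 1e-10)
  expect_equal(row$intercept, 0.004, tolerance = 1e-12)
})

test_that("insufficient aligned pairs are signalled", {
  params <- fake_params(2, alpha0 = 0.02)
  pred <- data.frame(window_start = params$window_start, lswi = c(0.1, 0.2))
  expect_error(fit_candidates(params, pred),
               class = "neeflux_insufficient_pairs")
  expect_error(fit_candidates(fake_params(5, alpha0 = 0.02),
                              data.frame(window_start = Sys.Date(), x = 1)),
               class = "neeflux_missing_column")
})
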