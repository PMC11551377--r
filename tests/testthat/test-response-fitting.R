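test_that("noiseless synthetic data is recovered exactly by the log-linear fit", {
  fit <- fit_q10(noiseless_obs(q10 = 8, e_ref = 2))
  expect_equal(fit$q10, 8, tolerance = 1e-10)
  expect_equal(fit$e_ref, 2, tolerance = 1e-10)
  expect_equal(fit$n_used, 16L)
  expect_s3_class(fit, "q10_fit")
})

test_that("observations above the fitting limit are excluded, not fitted", {
  obs <- noiseless_obs(q10 = 8, e_ref = 2)
  # distorted high-temperature points: emission destabilises above 35 degC
  distorted <- rbind(obs,
                     data.frame(t_leaf = c(38, 42), ppfd = 1000,
                                flux = c(1, 0.5)))
  fit_full <- fit_q10(obs)
  fit_dist <- fit_q10(distorted)
  expect_equal(fit_dist$q10, fit_full$q10, tolerance = 1e-12)
  expect_equal(fit_dist$e_ref, fit_full$e_ref, tolerance = 1e-12)
  expect_equal(fit_dist$n_excluded_temp, 2L)
  # the boundary itself is kept by default and droppable on request
  expect_equal(fit_q10(obs, inclusive = FALSE)$n_excluded_temp, 1L)
})

test_that("non-positive fluxes are excluded before the log transform", {
  obs <- rbind(noiseless_obs(),
               data.frame(t_leaf = c(22, 27), ppfd = 1000, flux = c(0, -1)))
  fit <- fit_q10(obs)
  expect_equal(fit$n_excluded_nonpos, 2L)
  expect_equal(fit$q10, 8, tolerance = 1e-10)
})

test_that("noisy synthetic data yields a Q10 close to truth", {
  obs <- gen_chamber_series(chamber_sim_config(
    true_q10 = 8, e_ref = 2, t_min = 20, t_max = 35, n_points = 30,
    noise_cv = 0.05, seed = 11))
  fit <- fit_q10(obs)
  expect_gt(fit$q10, 7.5)
  expect_lt(fit$q10, 8.5)
  expect_true(fit$q10_ci_low <= fit$q10 && fit$q10 <= fit$q10_ci_high)
})

test_that("fit is scale-invariant in flux and invariant to row order", {
  obs <- gen_chamber_series(chamber_sim_config(noise_cv = 0.05, seed = 3))
  fit <- fit_q10(obs)
  scaled <- obs; scaled$flux <- scaled$flux * 7
  fit_s <- fit_q10(scaled)
  expect_equal(fit_s$q10, fit$q10, tolerance = 1e-12)
  expect_equal(fit_s$e_ref, fit$e_ref * 7, tolerance = 1e-10)
  shuffled <- obs[sample.int(nrow(obs)), ]
  fit_p <- fit_q10(shuffled)
  expect_equal(fit_p$q10, fit$q10, tolerance = 1e-12)
})

test_that("fit errors are informative for unusable inputs", {
  one <- data.frame(t_leaf = 25, ppfd = 1000, flux = 2)
  expect_error(fit_q10(one), "fewer than 2")
  flat <- data.frame(t_leaf = c(25, 25, 25), ppfd = 1000, flux = c(1, 2, 3))
  expect_error(fit_q10(flat), "degenerate")
  hot <- data.frame(t_leaf = c(38, 40), ppfd = 1000, flux = c(1, 2))
  expect_error(fit_q10(hot), "fewer than 2")
})

test_that("seed-averaged Q10 recovery is nearly unbiased", {
  q10_hat <- vapply(1:20, function(s) {
    obs <- gen_chamber_series(chamber_sim_config(
      true_q10 = 7.2, e_ref = 2, t_min = 20, t_max = 35, n_points = 30,
      noise_cv = 0.1, seed = s))
    fit_q10(obs)$q10
  }, numeric(1))
  expect_lt(abs(mean(q10_hat) - 7.2) / 7.2, 0.02)
})

test_that("bootstrap CI is seeded-reproducible and brackets the estimate", {
  obs <- gen_chamber_series(chamber_sim_config(noise_cv = 0.1, seed = 5))
  b1 <- fit_q10(obs, ci_method = "bootstrap", n_boot = 200, seed = 9)
  b2 <- fit_q10(obs, ci_method = "bootstrap", n_boot = 200, seed = 9)
  expect_equal(b1$q10_ci_low, b2$q10_ci_low)
  expect_equal(b1$q10_ci_high, b2$q10_ci_high)
  expect_true(b1$q10_ci_low < b1$q10 && b1$q10 < b1$q10_ci_high)
})

test_that("nonlinear least squares agrees with the log-linear fit on clean data", {
  obs <- noiseless_obs(q10 = 6, e_ref = 3)
  fit_nls <- fit_q10(obs, method = "nls")
  expect_equal(fit_nls$q10, 6, tolerance = 1e-6)
  expect_equal(fit_nls$e_ref, 3, tolerance = 1e-6)
})

test_that("exponential activity factor satisfies its identities", {
  expect_identical(gamma_exponential(30, 7.2, 30), 1)
  expect_equal(gamma_exponential(40, 7.2, 30), 7.2)
  expect_equal(gamma_exponential(20, 4.0, 30), 0.25)
  expect_equal(gamma_exponential(35, 9.0, 30), 3.0)
  # decade multiplication property over a temperature grid
  tt <- seq(0, 45, by = 2.5)
  for (q in c(2, 3.7, 7.2, 12))
    expect_equal(gamma_exponential(tt + 10, q), q * gamma_exponential(tt, q),
                 tolerance = 1e-12)
  expect_error(gamma_exponential(30, -2), "q10")
})

test_that("effective Q10 summarises responses correctly", {
  g5 <- function(t) gamma_exponential(t, 5)
  for (iv in list(c(20, 30), c(17, 41), c(25, 35)))
    expect_equal(effective_q10(g5, iv[1], iv[2]), 5, tolerance = 1e-12)
  g_megan <- function(t) gamma_t_megan(t + 273.15, 297, 297)
  expect_equal(effective_q10(g_megan, 25, 35), 2.9791, tolerance = 1e-4)
  expect_gt(effective_q10(function(t) 1 + exp(0.1 * t), 10, 30), 1)
  expect_error(effective_q10(function(t) -1, 20, 30), "positive")
  expect_error(effective_q10(g5, 30, 20), "t_low")
})

test_that("normalized response equals 1 at the reference temperature", {
  fit <- fit_q10(noiseless_obs())
  curve <- normalized_response(fit, t_grid = c(20, 30, 40))
  expect_equal(curve$gamma[curve$t_leaf == 30], 1)
  expect_equal(curve$gamma, fit$q10^((curve$t_leaf - 30) / 10))
})
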