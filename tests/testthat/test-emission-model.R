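make_met <- function(t_air, ppfd, timestep_min = 360,
                     start = "2022-08-01 00:00:00") {
  data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_along(t_air) - 1) * timestep_min * 60,
    t_air = t_air, ppfd = ppfd)
}

test_that("trailing acclimation windows average correctly", {
  # 360-min step: the 24-h window spans 4 steps
  met <- make_met(t_air = c(300, 302, 304, 306, 308, 310),
                  ppfd = c(0, 1000, 1000, 0, 0, 500))
  acc <- rolling_acclimation(met)
  # expanding window at the series start
  expect_equal(acc$t24[1], 300)
  expect_equal(acc$t24[2], 301)
  # full window: mean of the trailing 4 steps
  expect_equal(acc$t24[5], mean(c(302, 304, 306, 308)))
  expect_equal(acc$t24[6], mean(c(304, 306, 308, 310)))
  # 240-h window exceeds the series: expanding mean of everything
  expect_equal(acc$t240[6], mean(met$t_air))
  # daytime-conditional PPFD mean: zeros at night do not dilute it
  expect_equal(acc$p24[1], 0)   # no daylight yet
  expect_equal(acc$p24[3], 1000)
  expect_equal(acc$p24[6], mean(c(1000, 500)))  # day steps in window 3:6
  expect_equal(acc$p240[6], mean(c(1000, 1000, 500)))
})

test_that("constant forcing gives constant acclimation fields", {
  met <- make_met(rep(300, 20), rep(800, 20), timestep_min = 60)
  acc <- rolling_acclimation(met)
  expect_true(all(acc$t24 == 300) && all(acc$t240 == 300))
  expect_true(all(acc$p24 == 800) && all(acc$p240 == 800))
})

test_that("irregular or reversed timestamps are rejected", {
  met <- make_met(rep(300, 4), rep(0, 4))
  met$timestamp[3] <- met$timestamp[3] + 123
  expect_error(rolling_acclimation(met), "uniform")
  met2 <- make_met(rep(300, 4), rep(0, 4))
  met2$timestamp <- rev(met2$timestamp)
  expect_error(rolling_acclimation(met2), "increasing")
})

test_that("MEGAN temperature activity hits its anchor points", {
  coef <- megan_coefficients()
  # at the temperature optimum the quotient collapses to 1, leaving Eopt
  expect_equal(gamma_t_megan(313, 297, 297), coef$eopt_base,
               tolerance = 1e-12)
  # standard conditions: leaf at 303 K, acclimation at 297 K
  expect_equal(gamma_t_megan(303, 297, 297), 1, tolerance = 0.01)
  expect_equal(gamma_t_megan(303.15, 297, 297), 1, tolerance = 0.02)
  # rising limb is monotone
  expect_gt(gamma_t_megan(308.15, 297, 297), gamma_t_megan(298.15, 297, 297))
  # warm acclimation shifts the optimum upward
  expect_equal(coef$topt_base + coef$topt_slope * 5,
               313 + 0.6 * 5)
  # overflow guard far above the optimum
  expect_true(is.finite(gamma_t_megan(400, 297, 297)))
  expect_gte(gamma_t_megan(400, 297, 297), 0)
  expect_error(gamma_t_megan(-3, 297, 297), "kelvin")
})

test_that("MEGAN light activity saturates and vanishes in the dark", {
  expect_identical(gamma_p(0, 200, 200), 0)
  expect_equal(gamma_p(1000, 200, 200), 0.9036, tolerance = 1e-4)
  # saturation asymptote is C_P
  coef <- megan_coefficients()
  alpha <- coef$alpha_base - coef$alpha_slope * log(200)
  c_p <- coef$cp_base * exp(coef$alpha_slope * (200 - 200)) * 200^0.6
  expect_equal(gamma_p(1e7, 200, 200), c_p, tolerance = 1e-3)
  expect_lt(gamma_p(1e7, 200, 200), c_p)
  # monotone in instantaneous light
  pp <- gamma_p(c(100, 400, 1000, 1800), 200, 200)
  expect_true(all(diff(pp) > 0))
  # no daylight history: zero, not log(0)
  expect_message(out <- gamma_p(500, 0, 0), "p240")
  expect_identical(out, 0)
  expect_error(gamma_p(-5, 200, 200), ">= 0")
})

test_that("leaf flux composes the factors linearly", {
  sedge <- species_params("sedge", 2, 3,
                          list(kind = "exponential", q10 = 7.2))
  megan <- species_params("tree", 2, 3, list(kind = "megan_default"))
  # darkness kills emission for both response kinds
  expect_equal(leaf_flux(sedge, 303.15, 0, 297, 297, 200, 200), 0)
  expect_equal(leaf_flux(megan, 303.15, 0, 297, 297, 200, 200), 0)
  # doubling the emission factor doubles the flux
  sedge2 <- species_params("sedge2", 4, 3,
                           list(kind = "exponential", q10 = 7.2))
  expect_equal(leaf_flux(sedge2, 305, 900, 297, 297, 200, 200),
               2 * leaf_flux(sedge, 305, 900, 297, 297, 200, 200))
  # at 30 degC the exponential temperature factor is exactly 1
  g_p <- gamma_p(900, 200, 200)
  expect_equal(leaf_flux(sedge, 273.15 + 30, 900, 297, 297, 200, 200),
               2 * 3 * g_p)
})

test_that("species parameter validation catches bad inputs", {
  expect_error(species_params("x", -1, 2), "emission_factor")
  expect_error(species_params("x", 1, 2, list(kind = "nope")), "kind")
  expect_error(species_params("x", 1, 2, list(kind = "exponential")), "q10")
})

test_that("flux simulation requires acclimation and is deterministic", {
  met_raw <- gen_met_series(met_sim_config(n_days_baseline = 2,
                                           n_days_heatwave = 1))
  sp <- species_params("s", 2, 2, list(kind = "exponential", q10 = 7.2))
  expect_error(simulate_flux_series(sp, met_raw), "rolling_acclimation")
  met <- rolling_acclimation(met_raw)
  f1 <- simulate_flux_series(sp, met)
  f2 <- simulate_flux_series(sp, met)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), nrow(met))
  expect_true(all(f1$flux >= 0))
  expect_true(all(f1$flux[met$ppfd == 0] == 0))
})

test_that("constant daytime conditions give constant daytime flux", {
  # 8 h of constant light and temperature: emission stays flat, no build-up
  met <- make_met(rep(294.15, 30), rep(1000, 30), timestep_min = 60)
  acc <- rolling_acclimation(met)
  sp <- species_params("s", 2, 1, list(kind = "exponential", q10 = 7.2))
  fx <- simulate_flux_series(sp, acc)
  expect_equal(diff(range(fx$flux)), 0, tolerance = 1e-12)
})

test_that("all-dark series yields identically zero flux", {
  met <- rolling_acclimation(make_met(rep(300, 8), rep(0, 8)))
  sp <- species_params("s", 2, 2, list(kind = "megan_default"))
  expect_true(all(simulate_flux_series(sp, met)$flux == 0))
})

test_that("steeper Q10 amplifies the heat-wave flux rise more", {
  met <- small_heatwave_met(boost = 8)
  mk <- function(q10) simulate_flux_series(
    species_params(paste0("q", q10), 2, 2,
                   list(kind = "exponential", q10 = q10)), met)
  f_steep <- mk(7.2); f_mild <- mk(3.7)
  prds <- default_periods(f_steep)
  ratio <- function(f)
    summarize_period(f, prds$heatwave)$mean_flux /
    summarize_period(f, prds$baseline)$mean_flux
  expect_gt(ratio(f_steep), ratio(f_mild))
})

test_that("unknown or non-positive MEGAN coefficients are rejected", {
  expect_error(megan_coefficients(bogus = 1), "bogus")
  expect_error(megan_coefficients(c_t1 = -5), "positive")
  expect_error(megan_coefficients(c_t1 = 300), "c_t2 > c_t1")
})
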