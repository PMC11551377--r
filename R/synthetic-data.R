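#' Configuration for a synthetic leaf-chamber measurement series
#'
#' Describes a chamber experiment in which leaf temperature is stepped over a
#' range while emission is recorded, with the true response known by
#' construction: the noiseless emission at leaf temperature T is
#' `e_ref * true_q10^((T - 30) / 10)` (nmol m-2 s-1, reference 30 degrees C).
#' Noise is multiplicative lognormal with unit mean, so emission rates stay
#' positive and the error is proportional to the signal, as chamber flux data
#' typically are.
#'
#' @param true_q10 True Q10 of the generating curve (dimensionless, > 0).
#' @param e_ref Emission at 30 degrees C leaf temperature (nmol m-2 s-1).
#' @param t_min,t_max Leaf-temperature range covered (degrees C, `t_min < t_max`).
#' @param n_points Number of observations, evenly spaced on `[t_min, t_max]`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 for noiseless series).
#' @param ppfd Chamber light level (umol m-2 s-1), constant over the series.
#' @param seed Integer seed; identical configurations give identical series.
#'
#' @return A validated list of class `"chamber_sim_config"`.
#' @seealso [gen_chamber_series()]
#' @export
chamber_sim_config <- function(true_q10 = 7.2, e_ref = 2, t_min = 20,
                               t_max = 42, n_points = 24, noise_cv = 0.05,
                               ppfd = 1000, seed = 1L) {
  cfg <- list(true_q10 = true_q10, e_ref = e_ref, t_min = t_min, t_max = t_max,
              n_points = as.integer(n_points), noise_cv = noise_cv,
              ppfd = ppfd, seed = as.integer(seed))
  check_scalar(cfg$true_q10, "true_q10", positive = TRUE)
  check_scalar(cfg$e_ref, "e_ref", nonneg = TRUE)
  check_scalar(cfg$t_min, "t_min")
  check_scalar(cfg$t_max, "t_max")
  if (cfg$t_min >= cfg$t_max)
    stop("invalid chamber_sim_config: t_min must be < t_max", call. = FALSE)
  check_scalar(cfg$noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar(cfg$ppfd, "ppfd", nonneg = TRUE)
  if (cfg$n_points < 2L)
    stop("invalid chamber_sim_config: n_points must be >= 2", call. = FALSE)
  structure(cfg, class = "chamber_sim_config")
}

#' Generate a synthetic chamber emission series
#'
#' Leaf temperatures are evenly spaced on `[t_min, t_max]`; the noiseless
#' expectation of each flux lies exactly on
#' `e_ref * true_q10^((T - 30) / 10)`. With `noise_cv > 0` each flux is
#' multiplied by `exp(rnorm(1, -s^2/2, s))` with `s = sqrt(log(1 + cv^2))`,
#' i.e. lognormal noise with mean 1 and coefficient of variation `noise_cv`.
#' Equal configurations (including seed) yield bit-identical output.
#'
#' @param cfg A [chamber_sim_config()].
#' @return A data frame of emission observations with columns `t_leaf`
#'   (degrees C), `ppfd` (umol m-2 s-1) and `flux` (nmol m-2 s-1).
#' @examples
#' obs <- gen_chamber_series(chamber_sim_config(true_q10 = 8, noise_cv = 0))
#' fit_q10(obs)
#' @export
gen_chamber_series <- function(cfg) {
  if (!inherits(cfg, "chamber_sim_config"))
    cfg <- do.call(chamber_sim_config, as.list(cfg))
  t_leaf <- seq(cfg$t_min, cfg$t_max, length.out = cfg$n_points)
  mu <- cfg$e_ref * cfg$true_q10^((t_leaf - 30) / 10)
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- with_seed(cfg$seed,
                       exp(stats::rnorm(cfg$n_points, -sdlog^2 / 2, sdlog)))
    flux <- mu * noise
  } else {
    flux <- mu
  }
  data.frame(t_leaf = t_leaf, ppfd = rep(cfg$ppfd, cfg$n_points), flux = flux)
}

#' Configuration for a synthetic meteorological series with a heat wave
#'
#' A baseline block of `n_days_baseline` days is followed by a heat-wave block
#' of `n_days_heatwave` days during which `t_boost_heatwave` kelvin is added
#' uniformly to air temperature. Within each day, temperature follows a
#' sinusoid around the block mean (maximum at 14:00 local time) and PPFD a
#' half-sinusoid over a 12-h photoperiod (06:00-18:00) peaking at `ppfd_max`
#' at solar noon, zero at night.
#'
#' @param n_days_baseline,n_days_heatwave Length of each block in days (>= 1).
#' @param t_mean_baseline Baseline diurnal-mean air temperature (K).
#' @param t_amplitude Diurnal temperature amplitude (K).
#' @param t_boost_heatwave Uniform heat-wave temperature offset (K, >= 0).
#' @param ppfd_max Solar-noon PPFD (umol m-2 s-1).
#' @param timestep Record spacing in minutes; must divide 24 h.
#' @param t_noise_sd Standard deviation of optional additive gaussian
#'   temperature noise (K); 0 (the default) gives a deterministic series.
#' @param start Date-time of the first record (character or POSIXct, UTC).
#' @param seed Integer seed for the optional noise.
#'
#' @return A validated list of class `"met_sim_config"`.
#' @export
met_sim_config <- function(n_days_baseline = 14, n_days_heatwave = 7,
                           t_mean_baseline = 296.15, t_amplitude = 6,
                           t_boost_heatwave = 8, ppfd_max = 2000,
                           timestep = 30, t_noise_sd = 0,
                           start = "2022-08-15 00:00:00", seed = 1L) {
  cfg <- list(n_days_baseline = as.integer(n_days_baseline),
              n_days_heatwave = as.integer(n_days_heatwave),
              t_mean_baseline = t_mean_baseline, t_amplitude = t_amplitude,
              t_boost_heatwave = t_boost_heatwave, ppfd_max = ppfd_max,
              timestep = timestep, t_noise_sd = t_noise_sd,
              start = as.POSIXct(start, tz = "UTC"), seed = as.integer(seed))
  if (cfg$n_days_baseline < 1L)
    stop("invalid met_sim_config: n_days_baseline must be >= 1", call. = FALSE)
  if (cfg$n_days_heatwave < 1L)
    stop("invalid met_sim_config: n_days_heatwave must be >= 1", call. = FALSE)
  check_scalar(cfg$t_boost_heatwave, "t_boost_heatwave", nonneg = TRUE)
  check_scalar(cfg$ppfd_max, "ppfd_max", nonneg = TRUE)
  check_scalar(cfg$t_amplitude, "t_amplitude", nonneg = TRUE)
  check_scalar(cfg$t_noise_sd, "t_noise_sd", nonneg = TRUE)
  check_scalar(cfg$timestep, "timestep", positive = TRUE)
  if (abs(1440 / cfg$timestep - round(1440 / cfg$timestep)) > 1e-9)
    stop("invalid met_sim_config: timestep must divide 24 h", call. = FALSE)
  structure(cfg, class = "met_sim_config")
}

#' Generate a synthetic meteorological forcing series
#'
#' @param cfg A [met_sim_config()].
#' @return A data frame with columns `timestamp` (POSIXct, regular step),
#'   `t_air` (K) and `ppfd` (umol m-2 s-1), carrying attributes
#'   `heatwave_start` and `heatwave_end` (the half-open heat-wave interval)
#'   and `timestep_min`.
#' @examples
#' met <- gen_met_series(met_sim_config(n_days_baseline = 2, n_days_heatwave = 1))
#' range(met$t_air)
#' @export
gen_met_series <- function(cfg) {
  if (!inherits(cfg, "met_sim_config"))
    cfg <- do.call(met_sim_config, as.list(cfg))
  steps_day <- as.integer(round(1440 / cfg$timestep))
  n_days <- cfg$n_days_baseline + cfg$n_days_heatwave
  n <- n_days * steps_day
  timestamp <- cfg$start + (seq_len(n) - 1L) * cfg$timestep * 60
  hour <- (as.numeric(timestamp - cfg$start, units = "hours")) %% 24
  day_index <- (seq_len(n) - 1L) %/% steps_day
  in_heatwave <- day_index >= cfg$n_days_baseline

  # diurnal sinusoid: maximum at 14:00, minimum at 02:00
  t_air <- cfg$t_mean_baseline +
    cfg$t_amplitude * sin(2 * pi * (hour - 8) / 24) +
    ifelse(in_heatwave, cfg$t_boost_heatwave, 0)
  if (cfg$t_noise_sd > 0)
    t_air <- t_air + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$t_noise_sd))

  # half-sinusoid photoperiod 06:00-18:00, zero at night
  ppfd <- cfg$ppfd_max * pmax(0, sin(pi * (hour - 6) / 12))
  ppfd[hour < 6 | hour > 18] <- 0

  met <- data.frame(timestamp = timestamp, t_air = t_air, ppfd = ppfd)
  attr(met, "heatwave_start") <- cfg$start + cfg$n_days_baseline * 86400
  attr(met, "heatwave_end") <- cfg$start + n_days * 86400
  attr(met, "timestep_min") <- cfg$timestep
  met
}

# Run code with a temporary RNG state so generators are seeded without
# clobbering the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("invalid config: %s must be a finite number", name),
         call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("invalid config: %s must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("invalid config: %s must be >= 0", name), call. = FALSE)
  invisible(TRUE)
}
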