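# shared fixtures, built in code

# noiseless chamber series on a known exponential curve
noiseless_obs <- function(q10 = 8, e_ref = 2, t_min = 20, t_max = 35,
                          n = 16) {
  gen_chamber_series(chamber_sim_config(true_q10 = q10, e_ref = e_ref,
                                        t_min = t_min, t_max = t_max,
                                        n_points = n, noise_cv = 0))
}

# small deterministic heat-wave forcing with acclimation fields
small_heatwave_met <- function(boost = 8, timestep = 60) {
  rolling_acclimation(gen_met_series(met_sim_config(
    n_days_baseline = 6, n_days_heatwave = 3, t_boost_heatwave = boost,
    timestep = timestep)))
}

# flux data frame on an hourly grid
flux_df <- function(flux, start = "2022-08-15 00:00:00") {
  data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_along(flux) - 1) * 3600,
    flux = flux)
}
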