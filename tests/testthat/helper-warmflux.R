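# Small configurations for fast unit tests; acceptance checks use the
# full default configuration.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_years = 1L, chambers_per_plot = 2L,
             closures_per_day = 2L, ...)
}

two_year_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_years = 2L, ...)
}

# Manually built closure series with a prescribed linear concentration rise
# (nmol mol-1 per hour) over the full record; ambient_C set so the dilution
# term vanishes unless requested.
linear_closure <- function(slope_per_h, species = "NO", ambient = 1,
                           T_K = 273, P_hPa = 1013, dilution_zero = TRUE,
                           geometry = chamber_geometry()) {
  t_s <- seq(0, geometry$closure_duration_min * 60, by = geometry$dt_s)
  conc <- ambient + slope_per_h * t_s / 3600
  phase <- ifelse(t_s < geometry$flush_min * 60, "flush", "closure")
  window <- warmflux:::regression_window(species)
  inwin <- phase == "closure" & t_s >= window[1] & t_s <= window[2]
  amb <- if (dilution_zero) mean(conc[inwin]) else ambient
  structure(list(
    samples = data.frame(t_s = t_s, conc = conc, phase = phase),
    species = species, T_K = T_K, P_hPa = P_hPa, ambient_C = amb,
    geometry = geometry, chamber_id = "ch1", plot_id = "p1",
    treatment = "control", true_flux = NA_real_
  ), class = "closure_series")
}

# Daily flux table with a constant value over given days, one treatment.
constant_daily <- function(value, species = "N2O", treatment = "control",
                           doys = 1:365, years = 1L) {
  expand <- expand.grid(doy = doys, year = years)
  data.frame(year = expand$year, doy = expand$doy, treatment = treatment,
             species = species, mean_flux = value, se = 0,
             n_fluxes = 1L, n_chambers = 1L, n_excluded = 0L)
}
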