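#' True flux response surface of the synthetic generator
#'
#' The noiseless flux (ug N m-2 h-1) emitted by the synthetic soil at a given
#' temperature and moisture. NO follows an exponential temperature term times
#' a downward-parabolic moisture factor peaking at `moisture_optimum`
#' (clipped at zero), and is shut off in frozen soil. N2O follows its own
#' exponential temperature term times a moisture-increasing factor
#' (WFPS / optimum), plus an additive freeze-thaw pulse that decays
#' exponentially over `pulse_decay_days` after thaw and is confined to four
#' decay times (the burst is a transient substrate release near 0 degrees C,
#' so it carries no temperature factor). The `substrate` multiplier carries
#' slow substrate-supply limitation (see [substrate_multiplier()]); it
#' defaults to 1.
#'
#' By construction the ratio of NO fluxes 10 degrees C apart (moisture fixed)
#' equals the configured Q10. The function never returns NaN.
#'
#' @param temp soil temperature (degrees C).
#' @param wfps water-filled pore space (%), in `[0, 100]`.
#' @param species `"NO"` or `"N2O"`.
#' @param config a [sim_config()].
#' @param days_since_thaw days since the spring thaw anchor (`Inf` = no
#'   pulse); recycled against `temp`.
#' @param substrate substrate-supply multiplier (>= 0).
#' @param frozen logical; frozen soil emits no NO.
#' @return flux in ug N m-2 h-1, never NaN.
#' @export
true_flux_surface <- function(temp, wfps, species, config,
                              days_since_thaw = Inf, substrate = 1,
                              frozen = FALSE) {
  species <- match_species(species)
  if (any(wfps < 0 | wfps > 100, na.rm = TRUE))
    stop("wfps must lie in [0, 100]")
  A <- config$baseline_amplitude_A[[species]]
  opt <- config$moisture_optimum
  if (species == "NO") {
    g <- pmax(0, 1 + config$moisture_curvature * (wfps - opt)^2)
    base <- A * substrate * exp(config$temp_coefficient_k * temp) * g
    # post-thaw substrate flush: nitrification NO burst, not moisture-gated
    pulse <- pulse_amp(config, "NO") * substrate *
      pulse_shape(days_since_thaw, config$pulse_decay_days)
    flux <- (base + pulse) * ifelse(frozen, 0, 1)
  } else {
    h <- wfps / opt
    base <- A * substrate * exp(config$temp_coefficient_k_n2o * temp) * h
    pulse <- pulse_amp(config, "N2O") * substrate * h *
      pulse_shape(days_since_thaw, config$pulse_decay_days)
    flux <- base + pulse
  }
  flux[is.na(flux)] <- 0
  flux
}

# Exponential-decay pulse shape, active for four decay times after thaw.
pulse_shape <- function(days_since_thaw, decay_days) {
  active <- is.finite(days_since_thaw) & days_since_thaw >= 0 &
    days_since_thaw <= 4 * decay_days
  ifelse(active, exp(-pmax(days_since_thaw, 0) / decay_days), 0)
}

# Per-species pulse amplitude; a single unnamed value applies to N2O only
# (the dominant freeze-thaw emitter).
pulse_amp <- function(config, species) {
  pa <- config$pulse_amplitude
  if (length(pa) > 1L && !is.null(names(pa))) pa[[species]]
  else if (species == "N2O") pa[[1]] else 0
}

#' Substrate-supply multiplier from organic-horizon moisture
#'
#' Relative substrate availability for nitrification/denitrification as a
#' power function of growing-season organic-horizon moisture:
#' `(m_O / reference) ^ substrate_exponent`. Substrate pools integrate
#' moisture slowly, so the multiplier is evaluated per plot and year on the
#' growing-season mean rather than daily, leaving the daily apparent
#' temperature sensitivity untouched.
#'
#' @param m_o growing-season mean gravimetric O-horizon moisture (g g-1).
#' @param config a [sim_config()].
#' @param species `"NO"` or `"N2O"` (the exponents differ: nitrification-
#'   driven NO is more substrate-limited).
#' @return multiplier (1 at the reference moisture).
#' @export
substrate_multiplier <- function(m_o, config, species = "NO") {
  ex <- config$substrate_exponent
  ex <- if (length(ex) > 1L) ex[[match_species(species)]] else ex[[1]]
  (m_o / config$o_moisture_reference)^ex
}

# Per plot-day-species true fluxes from a climate table.
daily_true_fluxes <- function(climate, config,
                              species = c("NO", "N2O")) {
  gs <- doy_in_growing_season(climate$doy)
  key <- interaction(climate$plot_id, climate$year, drop = TRUE)
  m_gs <- tapply(climate$grav_o[gs], key[gs], mean)
  m_day <- as.numeric(m_gs[as.character(key)])
  out <- lapply(species, function(sp) {
    sub <- substrate_multiplier(m_day, config, sp)
    data.frame(
      plot_id = climate$plot_id, treatment = climate$treatment,
      year = climate$year, doy = climate$doy, day = climate$day,
      species = sp,
      temp_mineral = climate$temp_mineral, wfps = climate$wfps,
      true_flux = true_flux_surface(
        climate$temp_mineral, climate$wfps, sp, config,
        days_since_thaw = climate$days_since_thaw,
        substrate = sub, frozen = climate$frozen
      )
    )
  })
  do.call(rbind, out)
}

#' Simulate a laboratory incubation set
#'
#' Before/after NH4+ and NO3- pools for soils of both layers and treatments
#' incubated at a temperature gradient (default 5, 10, 15, 20, 25 degrees C)
#' for one week, generated from an Arrhenius-form rate law
#' `R = a * exp(b * T)`. Net mineralization adds to the combined inorganic-N
#' pool and net nitrification transfers NH4+ to NO3-, so the generated pools
#' invert exactly to the configured rates when noise is off. Warmed-treatment
#' soils receive rate multipliers below one in the organic horizon only,
#' reflecting substrate limitation from surface drying; moisture is held at
#' its initial value, so the simulator has no moisture dynamics.
#'
#' @param config a [sim_config()]; see its `incubation` parameter list.
#' @return data.frame with columns `sample_id`, `layer`, `treatment`,
#'   `temp_C`, `nh4_before`, `no3_before`, `nh4_after`, `no3_after`, `days`.
#' @export
simulate_incubation <- function(config) {
  config <- validate_sim_config(config)
  inc <- config$incubation
  set.seed(derive_seed(config$seed, "incubation"))
  grid <- expand.grid(
    rep = seq_len(inc$n_reps), temp_C = inc$temperatures,
    treatment = c("control", "warmed"), layer = c("O", "mineral"),
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  warm_o <- grid$treatment == "warmed" & grid$layer == "O"
  mult_m <- ifelse(warm_o, inc$warm_multiplier_miner, 1)
  mult_n <- ifelse(warm_o, inc$warm_multiplier_nitr, 1)
  a_m <- inc$a_miner[grid$layer] * mult_m
  a_n <- inc$a_nitr[grid$layer] * mult_n
  r_miner <- a_m * exp(inc$b * grid$temp_C)
  r_nitr <- a_n * exp(inc$b * grid$temp_C)

  nh4_before <- pmax(rnorm(n, ifelse(grid$layer == "O", 8, 3), 0.5), 0.5)
  no3_before <- pmax(rnorm(n, ifelse(grid$layer == "O", 4, 2), 0.4), 0.3)
  d <- inc$days
  nh4_after <- nh4_before + (r_miner - r_nitr) * d + rnorm(n, 0, inc$noise_sd)
  no3_after <- no3_before + r_nitr * d + rnorm(n, 0, inc$noise_sd)
  data.frame(
    sample_id = sprintf("%s_%s_T%02d_r%d", grid$layer, grid$treatment,
                        grid$temp_C, grid$rep),
    layer = grid$layer, treatment = grid$treatment, temp_C = grid$temp_C,
    nh4_before = nh4_before, no3_before = no3_before,
    nh4_after = pmax(nh4_after, 0), no3_after = pmax(no3_after, 0),
    days = d
  )
}
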