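#' Run a full synthetic warming experiment
#'
#' Chains the generator end-to-end: soil climate, true flux surfaces,
#' chamber-level measurements, and daily treatment aggregation.
#'
#' `measurement = "closure"` pushes every chamber-day through the full
#' measurement chain: per-chamber lognormal flux heterogeneity, simulation
#' of each 20-min closure via the vented-chamber mass balance with analyzer
#' noise, and flux recovery with the accumulation + dynamic estimator
#' ([compute_flux()] semantics, vectorized). `measurement = "daily"`
#' shortcuts the closure layer and records the heterogeneous chamber fluxes
#' directly — the estimator's fidelity is established separately, so
#' treatment-contrast studies over many seeds use this path.
#'
#' @param config a [sim_config()].
#' @param measurement `"daily"` or `"closure"`.
#' @param species species to simulate (default both).
#' @param treatments treatments to simulate (default both).
#' @return object of class `flux_experiment`: list with `config`, `climate`,
#'   `soil_daily` (treatment-level daily temperature/WFPS/O-moisture),
#'   `true_fluxes`, `flux_records` (chamber level), `daily_fluxes`
#'   (treatment level), and `delta_t` (realized growing-season mineral-soil
#'   warming; `NA` unless both treatments were run).
#' @export
simulate_experiment <- function(config,
                                measurement = c("daily", "closure"),
                                species = c("NO", "N2O"),
                                treatments = c("control", "warmed")) {
  config <- validate_sim_config(config)
  measurement <- match.arg(measurement)
  species <- match.arg(species, c("NO", "N2O"), several.ok = TRUE)

  climate <- simulate_climate(config)
  climate_use <- climate[climate$treatment %in% treatments, , drop = FALSE]
  soil_daily <- aggregate(
    cbind(temp_mineral, wfps, grav_o) ~ year + doy + treatment,
    data = climate, FUN = mean)

  tf <- daily_true_fluxes(climate_use, config, species)
  geometry <- chamber_geometry()
  plot_ids <- unique(climate_use$plot_id)
  records <- vector("list", length(plot_ids) * config$chambers_per_plot *
                      length(species))
  ri <- 0L
  for (sp in species) {
    for (pi in seq_along(plot_ids)) {
      p <- plot_ids[pi]
      sub <- tf[tf$plot_id == p & tf$species == sp, , drop = FALSE]
      sub <- sub[order(sub$day), ]
      n_d <- nrow(sub)
      pair <- as.integer(sub("^[CW]", "", p))   # matched-pair index
      for (ch in seq_len(config$chambers_per_plot)) {
        unit <- (pair - 1L) * 100L + ch + 10000L * (sp == "N2O")
        set.seed(derive_seed(config$seed, "chamber", unit))
        eta <- exp(rnorm(n_d, 0, config$chamber_lnsd) -
                     config$chamber_lnsd^2 / 2)
        chamber_flux <- sub$true_flux * eta
        ri <- ri + 1L
        if (measurement == "daily") {
          records[[ri]] <- data.frame(
            chamber_id = sprintf("%s_ch%d", p, ch), plot_id = p,
            treatment = sub$treatment, species = sp,
            year = sub$year, doy = sub$doy,
            flux = chamber_flux, flux_true = chamber_flux,
            qc_flags = "", stringsAsFactors = FALSE
          )
        } else {
          ncl <- config$closures_per_day
          idx <- rep(seq_len(n_d), each = ncl)
          est <- simulate_and_estimate_closures(
            flux = chamber_flux[idx], species = sp, T_C = sub$temp_mineral[idx],
            config = config, geometry = geometry,
            seed = derive_seed(config$seed, "closure", unit))
          records[[ri]] <- data.frame(
            chamber_id = sprintf("%s_ch%d", p, ch), plot_id = p,
            treatment = sub$treatment[idx], species = sp,
            year = sub$year[idx], doy = sub$doy[idx],
            flux = est$flux, flux_true = est$flux_true,
            qc_flags = "", stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  records <- do.call(rbind, records[seq_len(ri)])
  daily <- daily_aggregate(records)

  delta_t <- NA_real_
  if (all(c("control", "warmed") %in% treatments)) {
    gs <- soil_daily[doy_in_growing_season(soil_daily$doy), ]
    tm <- tapply(gs$temp_mineral, gs$treatment, mean)
    delta_t <- unname(tm["warmed"] - tm["control"])
  }
  structure(list(
    config = config, climate = climate, soil_daily = soil_daily,
    true_fluxes = tf, flux_records = records, daily_fluxes = daily,
    delta_t = delta_t
  ), class = "flux_experiment")
}

#' @export
print.flux_experiment <- function(x, ...) {
  cat(sprintf(
    "<flux_experiment> %d y, %d plot-series, %d chamber flux records (%s), delta_T = %s C\n",
    x$config$n_years, length(unique(x$climate$plot_id)),
    nrow(x$flux_records), paste(unique(x$flux_records$species), collapse = "+"),
    ifelse(is.na(x$delta_t), "NA", sprintf("%.2f", x$delta_t))))
  invisible(x)
}

#' Apparent Q10 of a simulated experiment
#'
#' Convenience wrapper for the analysis used on ambient (control) data:
#' merge daily fluxes with daily soil state, bin at 0.5 degrees C over the
#' growing season, and fit the exponential temperature response.
#'
#' @param experiment a `flux_experiment`.
#' @param species species to analyse (default `"NO"`).
#' @param treatment treatment to analyse (default `"control"`).
#' @param season day-of-year window (default growing season).
#' @return a `temp_response_fit`.
#' @export
apparent_q10 <- function(experiment, species = "NO", treatment = "control",
                         season = season_calendar()$growing) {
  daily <- experiment$daily_fluxes
  d <- merge(daily[daily$species == species & daily$treatment == treatment, ],
             experiment$soil_daily[c("year", "doy", "treatment",
                                     "temp_mineral", "wfps")],
             by = c("year", "doy", "treatment"))
  bins <- bin_fluxes(d, "temperature", season = season)
  fit_temperature_response(bins)
}
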