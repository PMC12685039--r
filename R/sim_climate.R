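#' Simulate daily soil climate for all plots
#'
#' Generates a per-plot daily series of soil temperature (organic horizon and
#' 0-10 cm mineral layer), precipitation, volumetric and gravimetric soil
#' moisture, WFPS, a frozen flag, and days-since-thaw, over `n_years`
#' 365-day years.
#'
#' The model is: a seasonal sinusoid plus AR(1) noise for temperature (about
#' -5 to 25 degrees C at 5 cm mineral depth); precipitation as a seasonally
#' inhomogeneous event process (~80 % of the annual total between May and
#' September, with occasional heavy events above the configured threshold);
#' and a bucket model for moisture in each layer (gain proportional to
#' precipitation, evapotranspiration loss proportional to temperature and to
#' current wetness, free drainage above field capacity in the mineral layer).
#' All plots share one weather realization; plot microsites add small
#' paired offsets (plot j of the warmed treatment shares the microsite stream
#' of control plot j, a matched-pair layout), so a null treatment
#' (`warming_delta_T = 0`) yields byte-identical control and warmed series.
#'
#' Warmed plots receive a `+warming_delta_T` offset and an evapotranspiration
#' multiplier calibrated (deterministic bucket, `uniroot`) so the realized
#' growing-season moisture deficits match the configured relative changes.
#' The freeze-thaw anchor of warmed plots is advanced by a uniform draw from
#' `thaw_advance_days` when `warming_delta_T > 0`.
#'
#' @param config a [sim_config()].
#' @return A `climate_series` data.frame with columns `plot_id`, `treatment`,
#'   `year`, `doy`, `day`, `temp_o`, `temp_mineral`, `precip_mm`,
#'   `grav_o`, `vwc_mineral`, `wfps`, `frozen`, `days_since_thaw`.
#'   Attributes: `config`, `thaw_table`, `et_multipliers`.
#' @export
simulate_climate <- function(config) {
  config <- validate_sim_config(config)
  n_days <- config$n_years * DAYS_PER_YEAR
  doy <- rep(seq_len(DAYS_PER_YEAR), config$n_years)
  year <- rep(seq_len(config$n_years), each = DAYS_PER_YEAR)

  wx <- simulate_weather(config, n_days, doy)

  np <- config$n_plots_per_treatment
  plots <- data.frame(
    plot_id = c(sprintf("C%d", seq_len(np)), sprintf("W%d", seq_len(np))),
    treatment = rep(c("control", "warmed"), each = np),
    pair = rep(seq_len(np), 2L)
  )

  et_mult <- calibrate_et_multipliers(config, wx)

  out <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    warmed <- p$treatment == "warmed"
    set.seed(derive_seed(config$seed, "plot", p$pair))
    t_off <- rnorm(1, 0, 0.1)
    vwc_noise <- exp(rnorm(n_days, 0, 0.02))
    grav_noise <- exp(rnorm(n_days, 0, 0.03))
    adv <- 0
    if (config$warming_delta_T > 0) {
      adv_draw <- round(runif(1, config$thaw_advance_days[1],
                              config$thaw_advance_days[2]))
      if (warmed) adv <- adv_draw
    }
    dT <- if (warmed) config$warming_delta_T else 0
    temp_min <- wx$temp_mineral + t_off + dT
    temp_o <- wx$temp_o + t_off + dT

    # a configured zero moisture change switches the moisture pathway off:
    # the warmed plot reuses its control pair's moisture series verbatim
    # (temperature-only "Model A" limit); otherwise the calibrated
    # evapotranspiration multiplier realizes the configured deficit
    mult <- if (warmed) et_mult else c(O = 1, mineral = 1)
    t_moist_min <- if (config$relative_moisture_change_mineral == 0)
      temp_min - dT else temp_min
    t_moist_o <- if (config$relative_moisture_change_O == 0)
      temp_o - dT else temp_o
    m_min <- if (config$relative_moisture_change_mineral == 0)
      c(O = 1, mineral = 1)[["mineral"]] else mult[["mineral"]]
    m_o <- if (config$relative_moisture_change_O == 0) 1 else mult[["O"]]
    vwc <- bucket_mineral(t_moist_min, wx$precip, config, m_min)
    grav <- bucket_organic(t_moist_o, wx$precip, config, m_o)
    vwc_obs <- pmin(vwc * vwc_noise, mineral_porosity(config))
    grav_obs <- grav * grav_noise

    thaw <- thaw_days(temp_min - dT, year)  # control-pair thaw anchor
    dst <- days_since_thaw(thaw - adv, year, doy)

    out[[i]] <- data.frame(
      plot_id = p$plot_id, treatment = p$treatment, year = year, doy = doy,
      day = seq_len(n_days),
      temp_o = temp_o, temp_mineral = temp_min, precip_mm = wx$precip,
      grav_o = grav_obs, vwc_mineral = vwc_obs,
      wfps = compute_wfps(vwc_obs, config$bd),
      frozen = temp_min <= 0,
      days_since_thaw = dst
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  attr(res, "et_multipliers") <- et_mult
  class(res) <- c("climate_series", "data.frame")
  res
}

mineral_porosity <- function(config) {
  1 - config$bd / physical_constants$particle_density
}

# Shared weather realization: mineral/organic soil temperature and daily
# precipitation (mm). One substream; identical for every plot.
simulate_weather <- function(config, n_days, doy) {
  set.seed(derive_seed(config$seed, "weather"))
  seas <- cos(2 * pi * (doy - 205) / DAYS_PER_YEAR)
  ar <- numeric(n_days)
  eps <- rnorm(n_days, 0, 0.75)
  for (d in 2:n_days) ar[d] <- 0.8 * ar[d - 1] + eps[d]
  temp_mineral <- 10 + 15 * seas + ar
  temp_o <- 9.5 + 16 * seas + 1.1 * ar

  monsoon <- doy >= 121 & doy <= 273          # May 1 .. Sep 30
  p_wet <- ifelse(monsoon, 0.45, 0.25)
  mean_amt <- ifelse(monsoon, 9.44, 3.0)
  wet <- runif(n_days) < p_wet
  shape <- 0.55
  amt <- stats::rgamma(n_days, shape = shape, scale = mean_amt / shape)
  precip <- ifelse(wet, amt, 0) * config$mean_annual_precip_mm / 811
  list(temp_mineral = temp_mineral, temp_o = temp_o, precip = precip)
}

# Deterministic bucket for the 0-10 cm mineral layer (VWC, m3 m-3). Winter
# precipitation accumulates as a snowpack and infiltrates over the days
# after thaw, producing the observed early-spring moisture rise.
bucket_mineral <- function(temp, precip, config, et_mult = 1,
                           gain_per_mm = 0.0025, et_coef = 0.0005,
                           field_capacity = 0.36, drain_rate = 0.6,
                           vwc0 = 0.30, melt_frac = 0.15) {
  n <- length(temp)
  porosity <- mineral_porosity(config)
  v <- numeric(n)
  v[1] <- vwc0
  pack <- 0
  for (d in 2:n) {
    frozen <- temp[d - 1] <= 0
    if (frozen) {
      pack <- pack + precip[d - 1]
      v[d] <- v[d - 1]
      next
    }
    melt <- melt_frac * pack
    pack <- pack - melt
    gain <- gain_per_mm * (precip[d - 1] + melt)
    et <- et_coef * max(temp[d - 1], 0) * (v[d - 1] / 0.28) * et_mult
    drain <- drain_rate * max(v[d - 1] - field_capacity, 0)
    v[d] <- min(max(v[d - 1] + gain - et - drain, 0.05), porosity)
  }
  v
}

# Deterministic bucket for the organic horizon (gravimetric, g H2O g-1).
bucket_organic <- function(temp, precip, config, et_mult = 1,
                           gain_per_mm = 0.016, et_coef = 0.0028,
                           m0 = 0.81, melt_frac = 0.15) {
  n <- length(temp)
  ref <- config$o_moisture_reference
  m <- numeric(n)
  m[1] <- m0
  pack <- 0
  for (d in 2:n) {
    frozen <- temp[d - 1] <= 0
    if (frozen) {
      pack <- pack + precip[d - 1]
      m[d] <- m[d - 1]
      next
    }
    melt <- melt_frac * pack
    pack <- pack - melt
    gain <- gain_per_mm * (precip[d - 1] + melt)
    et <- et_coef * max(temp[d - 1], 0) * (m[d - 1] / ref) * et_mult
    m[d] <- min(max(m[d - 1] + gain - et, 0.20), 1.30)
  }
  m
}

# Calibrate warmed-plot evapotranspiration multipliers so the deterministic
# bucket's growing-season deficit hits the configured relative changes,
# scaled by warming_delta_T / 2 so a null treatment has no drying.
calibrate_et_multipliers <- function(config, wx) {
  if (config$warming_delta_T == 0)
    return(c(O = 1, mineral = 1))
  n_days <- length(wx$temp_mineral)
  doy <- rep(seq_len(DAYS_PER_YEAR), length.out = n_days)
  gs <- doy_in_growing_season(doy)
  scale <- config$warming_delta_T / 2.0

  target_one <- function(target_rel, run) {
    target <- target_rel * scale
    if (target_rel == 0) return(1)  # moisture pathway bypassed upstream
    base <- mean(run(1, warmed = FALSE)[gs])
    f <- function(m) mean(run(m, warmed = TRUE)[gs]) / base - (1 + target)
    stats::uniroot(f, c(0.25, 6), tol = 1e-4)$root
  }
  run_min <- function(m, warmed) {
    dT <- if (warmed) config$warming_delta_T else 0
    bucket_mineral(wx$temp_mineral + dT, wx$precip, config, m)
  }
  run_o <- function(m, warmed) {
    dT <- if (warmed) config$warming_delta_T else 0
    bucket_organic(wx$temp_o + dT, wx$precip, config, m)
  }
  c(O = target_one(config$relative_moisture_change_O, run_o),
    mineral = target_one(config$relative_moisture_change_mineral, run_min))
}

# First day-of-year of sustained spring thaw (3 consecutive days above 0 C)
# per year, from a temperature series. Returns a vector indexed by year.
thaw_days <- function(temp, year) {
  vapply(split(temp, year), function(tv) {
    above <- tv > 0
    runs <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
    idx <- which(runs[seq_len(200)])  # spring half-year only
    if (length(idx)) idx[1] else 60L
  }, numeric(1))
}

days_since_thaw <- function(thaw_by_year, year, doy) {
  anchor <- thaw_by_year[year]
  dst <- doy - anchor
  dst[dst < 0] <- Inf          # before thaw
  dst[doy > 200] <- Inf        # autumn/winter: no spring pulse
  dst
}

#' Convert a climate series to long per-layer soil records
#'
#' Reshapes the wide per-plot climate table into the soil-record layout used
#' by [treatment_profile()] and the soil CSV schema: one row per plot, day
#' and layer, with temperature and moisture in the layer's native units
#' (gravimetric for the organic horizon, VWC for the mineral layer).
#'
#' @param climate a `climate_series` from [simulate_climate()].
#' @return data.frame with columns `year`, `doy`, `plot_id`, `treatment`,
#'   `layer`, `temperature`, `moisture`, `bd`, `wfps`.
#' @export
soil_records <- function(climate) {
  cfg <- attr(climate, "config")
  bd <- if (!is.null(cfg)) cfg$bd else 0.70
  o <- data.frame(
    year = climate$year, doy = climate$doy, plot_id = climate$plot_id,
    treatment = climate$treatment, layer = "O",
    temperature = climate$temp_o, moisture = climate$grav_o,
    bd = NA_real_, wfps = NA_real_
  )
  m <- data.frame(
    year = climate$year, doy = climate$doy, plot_id = climate$plot_id,
    treatment = climate$treatment, layer = "mineral_0_10",
    temperature = climate$temp_mineral, moisture = climate$vwc_mineral,
    bd = bd, wfps = climate$wfps
  )
  rbind(o, m)
}
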