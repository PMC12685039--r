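#' Configuration for a synthetic warming experiment
#'
#' Collects every knob of the synthetic generator: experiment layout, warming
#' treatment, the true flux response surfaces, noise models, and the
#' site-climate parameterization. Defaults reproduce the conditions of a
#' 6-year, 2 degree C infrared-heater experiment in a temperate monsoon
#' forest: +2.0 degrees C at 5 cm mineral depth, growing-season moisture
#' reductions of 16 % (organic horizon) and 5 % (mineral 0-10 cm), heavy
#' (>= 30 mm) monsoon precipitation events, soil temperature spanning roughly
#' -5 to 25 degrees C, an NO temperature response with apparent Q10 = 3.5 and
#' a quadratic moisture optimum at 35 % WFPS, an N2O response with Q10 = 2.1
#' that increases with moisture in the growing season, and spring freeze-thaw
#' N2O pulses whose onset is advanced 8-11 days by warming.
#'
#' A single root `seed` fixes all outputs bit-for-bit; every plot x chamber
#' combination and every stage derives an independent substream from it, so
#' adding chambers does not perturb existing ones.
#'
#' @param seed integer root seed.
#' @param n_years number of simulated years (365-day calendar, no leap days).
#' @param n_plots_per_treatment plots per treatment (control / warmed).
#' @param chambers_per_plot automated chambers per plot.
#' @param closures_per_day chamber closures per chamber per day.
#' @param warming_delta_T warming magnitude at 5 cm mineral depth (degrees C,
#'   >= 0).
#' @param relative_moisture_change_O,relative_moisture_change_mineral realized
#'   growing-season relative moisture change under warming (fraction,
#'   negative = drying), per layer. The warmed evapotranspiration multiplier
#'   is calibrated against these targets; the drying scales with
#'   `warming_delta_T / 2` so a null treatment produces identical series.
#' @param temp_coefficient_k exponential temperature coefficient of the NO
#'   surface (per degree C); default `log(3.5)/10` (Q10 = 3.5).
#' @param temp_coefficient_k_n2o same for N2O; default `log(2.1)/10`.
#' @param moisture_optimum WFPS (%) at which the NO moisture factor peaks.
#' @param moisture_curvature curvature of the quadratic moisture factor
#'   (per (%WFPS)^2, negative); default `-1/35^2` puts the zeros at 0 and 70.
#' @param baseline_amplitude_A named vector, flux at 0 degrees C and optimal
#'   moisture (ug N m-2 h-1) per species.
#' @param substrate_exponent named per-species exponent linking the plot-year
#'   growing-season organic-horizon moisture (relative to
#'   `o_moisture_reference`) to the flux baseline; emulates moisture
#'   limitation of substrate supply. Nitrification-driven NO is more
#'   substrate-limited than denitrification-driven N2O, hence the larger
#'   default exponent for NO.
#' @param o_moisture_reference ambient organic-horizon gravimetric moisture
#'   (g H2O g-1) used as the substrate reference.
#' @param analyzer_noise_sd named vector, white analyzer noise per species
#'   (nmol mol-1).
#' @param chamber_lnsd log-scale SD of the mean-one lognormal chamber
#'   heterogeneity applied to daily true fluxes.
#' @param thaw_advance_days length-2 range (days); warmed-plot freeze-thaw
#'   pulse onset is advanced by a uniform draw from this range when
#'   `warming_delta_T > 0`.
#' @param heavy_precip_threshold heavy precipitation event size (mm).
#' @param pulse_amplitude named per-species peak of the post-thaw emission
#'   pulse (ug N m-2 h-1 at reference conditions), decaying over
#'   `pulse_decay_days`: a freeze-thaw denitrification burst for N2O and a
#'   smaller post-thaw nitrification (substrate flush) burst for NO.
#' @param pulse_decay_days e-folding time of the freeze-thaw pulse (days).
#' @param ambient_ppb named vector of ambient dry mole fractions
#'   (nmol mol-1); site values are not constrained by the experiment, these
#'   are conventional defaults.
#' @param bd mineral bulk density (g cm-3).
#' @param mean_annual_precip_mm annual precipitation (mm), ~80 % of which
#'   falls May-September.
#' @param incubation list of incubation-generator parameters: `a_miner`,
#'   `a_nitr` (rates at 0 degrees C, mg N kg-1 d-1, named by layer),
#'   `b` (per degree C), `warm_multiplier_miner`, `warm_multiplier_nitr`
#'   (O-horizon rate multipliers under warming; mineral layer unaffected),
#'   `noise_sd` (mg N kg-1 on post-incubation pools), `n_reps`, `days`,
#'   `temperatures`.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_years = 6L,
                       n_plots_per_treatment = 3L,
                       chambers_per_plot = 5L,
                       closures_per_day = 4L,
                       warming_delta_T = 2.0,
                       relative_moisture_change_O = -0.16,
                       relative_moisture_change_mineral = -0.05,
                       temp_coefficient_k = log(3.5) / 10,
                       temp_coefficient_k_n2o = log(2.1) / 10,
                       moisture_optimum = 35,
                       moisture_curvature = -1 / 35^2,
                       baseline_amplitude_A = c(NO = 1.0, N2O = 1.0),
                       substrate_exponent = c(NO = 2.6, N2O = 1.4),
                       o_moisture_reference = 0.81,
                       analyzer_noise_sd = c(NO = 0.2, N2O = 0.3),
                       chamber_lnsd = 0.35,
                       thaw_advance_days = c(8, 11),
                       heavy_precip_threshold = 30,
                       pulse_amplitude = c(NO = 17, N2O = 210),
                       pulse_decay_days = 14,
                       ambient_ppb = c(NO = 1, N2O = 330),
                       bd = 0.70,
                       mean_annual_precip_mm = 811,
                       incubation = list()) {
  inc <- utils::modifyList(list(
    a_miner = c(O = 0.30, mineral = 0.06),
    a_nitr = c(O = 0.18, mineral = 0.035),
    b = log(2) / 10,
    warm_multiplier_miner = 0.79,
    warm_multiplier_nitr = 0.86,
    noise_sd = 0.15,
    n_reps = 6L,
    days = 7,
    temperatures = c(5, 10, 15, 20, 25)
  ), incubation)
  cfg <- list(
    seed = as.integer(seed), n_years = as.integer(n_years),
    n_plots_per_treatment = as.integer(n_plots_per_treatment),
    chambers_per_plot = as.integer(chambers_per_plot),
    closures_per_day = as.integer(closures_per_day),
    warming_delta_T = warming_delta_T,
    relative_moisture_change_O = relative_moisture_change_O,
    relative_moisture_change_mineral = relative_moisture_change_mineral,
    temp_coefficient_k = temp_coefficient_k,
    temp_coefficient_k_n2o = temp_coefficient_k_n2o,
    moisture_optimum = moisture_optimum,
    moisture_curvature = moisture_curvature,
    baseline_amplitude_A = baseline_amplitude_A,
    substrate_exponent = substrate_exponent,
    o_moisture_reference = o_moisture_reference,
    analyzer_noise_sd = analyzer_noise_sd,
    chamber_lnsd = chamber_lnsd,
    thaw_advance_days = thaw_advance_days,
    heavy_precip_threshold = heavy_precip_threshold,
    pulse_amplitude = pulse_amplitude,
    pulse_decay_days = pulse_decay_days,
    ambient_ppb = ambient_ppb,
    bd = bd,
    mean_annual_precip_mm = mean_annual_precip_mm,
    incubation = inc
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_years <= 0L) stop("n_years must be positive")
  if (cfg$warming_delta_T < 0) stop("warming_delta_T must be >= 0")
  if (cfg$moisture_curvature >= 0) stop("moisture_curvature must be negative")
  rel <- c(cfg$relative_moisture_change_O, cfg$relative_moisture_change_mineral)
  if (any(rel <= -1 | rel >= 1)) stop("relative moisture changes must lie in (-1, 1)")
  if (!all(c("NO", "N2O") %in% names(cfg$baseline_amplitude_A)))
    stop("baseline_amplitude_A must be named for NO and N2O")
  if (length(cfg$thaw_advance_days) != 2L || diff(cfg$thaw_advance_days) < 0)
    stop("thaw_advance_days must be an increasing length-2 range")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d y | %d+%d plots x %d chambers x %d closures/day\n",
              x$seed, x$n_years, x$n_plots_per_treatment,
              x$n_plots_per_treatment, x$chambers_per_plot,
              x$closures_per_day))
  cat(sprintf("  warming +%.1f C; moisture change O %+.0f %%, mineral %+.0f %%\n",
              x$warming_delta_T, 100 * x$relative_moisture_change_O,
              100 * x$relative_moisture_change_mineral))
  cat(sprintf("  NO: A=%.2f, Q10=%.2f, optimum %.0f %% WFPS; N2O: A=%.2f, Q10=%.2f\n",
              x$baseline_amplitude_A[["NO"]], exp(10 * x$temp_coefficient_k),
              x$moisture_optimum, x$baseline_amplitude_A[["N2O"]],
              exp(10 * x$temp_coefficient_k_n2o)))
  invisible(x)
}

#' Serialize / read a simulation configuration as YAML
#'
#' The YAML document round-trips losslessly and carries the seed, so a config
#' file fully determines a synthetic experiment.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named vectors become YAML maps so names survive the round trip
  listify <- function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  x <- lapply(x, listify)
  x$incubation <- lapply(config$incubation, listify)
  yaml::write_yaml(x, path, precision = 22)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops names on length-1 vectors; restore named-vector fields
  for (f in c("baseline_amplitude_A", "analyzer_noise_sd", "ambient_ppb",
              "substrate_exponent", "pulse_amplitude"))
    raw[[f]] <- unlist(raw[[f]])
  raw$incubation <- lapply(raw$incubation, function(x)
    if (is.list(x)) unlist(x) else x)
  do.call(sim_config, raw)
}

# Deterministic substream seed derivation (root seed + stage + unit index).
# Plain modular mixing keeps every derived seed in [1, 2^31 - 2] and
# independent of how many other units exist.
derive_seed <- function(root, stage, unit = 0L) {
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  m <- 2147483647
  s <- (as.numeric(root) %% m) * 1000003 + stage_id * 10007 + as.numeric(unit) * 101
  as.integer(s %% (m - 1)) + 1L
}
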