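#' Physical constants used in flux and soil calculations
#'
#' Standard temperature, molar volume and pressure used to convert dry mole
#' fractions (nmol mol-1) to mass concentrations, the nitrogen mass per mole
#' of each gas, and the particle density of quartz used in the porosity term
#' of the WFPS formula.
#'
#' @format A list with elements `T0` (273 K), `V0` (22.4 L mol-1),
#'   `P0` (1013 hPa), `M_N` (named vector, g N per mol of gas: NO = 14,
#'   N2O = 28), and `particle_density` (2.65 g cm-3).
#' @export
physical_constants <- list(
  T0 = 273,                      # K
  V0 = 22.4,                     # L mol-1
  P0 = 1013,                     # hPa
  M_N = c(NO = 14, N2O = 28),    # g N mol-1 (N2O carries two N)
  particle_density = 2.65        # g cm-3, quartz
)

#' Mass-concentration conversion factor for a trace gas
#'
#' Converts a dry mole fraction of 1 nmol mol-1 to ug N m-3 at chamber
#' temperature and pressure: M/V0 * (P/P0) * (T0/T). At standard conditions
#' this is 0.625 ug N m-3 per nmol mol-1 for NO and 1.25 for N2O.
#'
#' @param species `"NO"` or `"N2O"`.
#' @param T_K chamber air temperature (K).
#' @param P_hPa chamber pressure (hPa).
#' @return ug N m-3 per nmol mol-1.
#' @export
conc_conversion <- function(species, T_K = physical_constants$T0,
                            P_hPa = physical_constants$P0) {
  species <- match_species(species)
  with(physical_constants,
       unname(M_N[species]) / V0 * (P_hPa / P0) * (T0 / T_K))
}

match_species <- function(species) {
  match.arg(species, c("NO", "N2O"))
}

# kg N ha-1 contributed by 1 ug N m-2 h-1 sustained for one day:
# 24 ug m-2 d-1 = 24e-9 kg / 1e-4 ha
KG_HA_PER_UG_M2_DAY <- 2.4e-4

# seconds of one simulated day; simulation calendar has 365 days, no leap days
DAYS_PER_YEAR <- 365L
GROWING_SEASON <- c(121L, 304L)  # May 1 .. Oct 31, day-of-year
SNOW_WINDOW <- c(335L, 90L)      # Dec 1 .. Mar 31 (wraps over new year)

doy_in_growing_season <- function(doy) {
  doy >= GROWING_SEASON[1] & doy <= GROWING_SEASON[2]
}

doy_in_snow_window <- function(doy) {
  doy >= SNOW_WINDOW[1] | doy <= SNOW_WINDOW[2]
}
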