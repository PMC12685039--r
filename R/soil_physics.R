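#' Water-filled pore space from volumetric water content
#'
#' WFPS (%) = VWC / (1 - BD / 2.65) * 100, the fraction of soil pore volume
#' occupied by water, using the bulk density `bd` and the particle density of
#' quartz (2.65 g cm-3) for total porosity. Values above 100 % (supersaturated
#' probe readings) are capped at 100 with a warning. Applies to mineral
#' layers; the organic horizon is tracked gravimetrically and has no WFPS.
#'
#' @param vwc volumetric water content (m3 m-3), in `[0, 1]`.
#' @param bd bulk density (g cm-3), must be below 2.65.
#' @return WFPS in percent, same length as `vwc`.
#' @seealso [invert_wfps()], [delta_wfps()]
#' @examples
#' compute_wfps(0.30, 0.70) # 40.77 %
#' @export
compute_wfps <- function(vwc, bd = 0.70) {
  stopifnot(is.numeric(vwc), is.numeric(bd))
  if (any(vwc < 0 | vwc > 1, na.rm = TRUE))
    stop("vwc must lie in [0, 1]")
  if (any(bd <= 0, na.rm = TRUE) ||
      any(bd >= physical_constants$particle_density, na.rm = TRUE))
    stop("bd must lie in (0, 2.65): porosity would be non-positive")
  porosity <- 1 - bd / physical_constants$particle_density
  wfps <- vwc / porosity * 100
  if (any(wfps > 100 + 1e-9, na.rm = TRUE)) {
    warning("WFPS above 100 % capped at saturation")
    wfps <- pmin(wfps, 100)
  }
  pmin(wfps, 100)
}

#' Invert WFPS back to volumetric water content
#'
#' @param wfps water-filled pore space (%).
#' @param bd bulk density (g cm-3).
#' @return VWC (m3 m-3).
#' @export
invert_wfps <- function(wfps, bd = 0.70) {
  porosity <- 1 - bd / physical_constants$particle_density
  wfps / 100 * porosity
}

#' Relative change in WFPS under warming
#'
#' (WFPS_warmed - WFPS_control) / WFPS_control * 100. Negative values mean
#' warming dried the soil.
#'
#' @param wfps_w WFPS in warmed plots (%).
#' @param wfps_c WFPS in control plots (%); must be positive.
#' @return relative change in percent.
#' @export
delta_wfps <- function(wfps_w, wfps_c) {
  if (any(wfps_c <= 0, na.rm = TRUE))
    stop("control WFPS must be positive")
  (wfps_w - wfps_c) / wfps_c * 100
}

#' Microbial biomass C and N from chloroform-fumigation flushes
#'
#' Converts the fumigated-minus-unfumigated extractable C and N flushes to
#' microbial biomass using extraction-efficiency factors kEC = 0.45 and
#' kEN = 0.54 (MB = flush / k). Negative flushes (analytical noise) are
#' flagged and returned as missing rather than as negative biomass.
#'
#' @param flush_c extractable C flush (ug C g-1 soil).
#' @param flush_n extractable N flush (ug N g-1 soil).
#' @param k_ec,k_en conversion factors.
#' @return data.frame with columns `mbc`, `mbn`, `flag`.
#' @export
microbial_biomass <- function(flush_c, flush_n, k_ec = 0.45, k_en = 0.54) {
  stopifnot(length(flush_c) == length(flush_n))
  bad_c <- !is.na(flush_c) & flush_c < 0
  bad_n <- !is.na(flush_n) & flush_n < 0
  mbc <- ifelse(bad_c, NA_real_, flush_c / k_ec)
  mbn <- ifelse(bad_n, NA_real_, flush_n / k_en)
  data.frame(
    mbc = mbc, mbn = mbn,
    flag = ifelse(bad_c | bad_n, "negative_flush", "")
  )
}

#' Warming effect on temperature and moisture by soil layer
#'
#' Summarizes a table of per-plot daily soil records into the
#' warmed-minus-control temperature difference (degrees C) and moisture
#' difference (native units: VWC for mineral layers, gravimetric water for the
#' organic horizon) per layer, with annual means and the across-year standard
#' error. Layers missing either treatment are skipped with a message.
#'
#' @param records data.frame with columns `year`, `doy`, `plot_id`,
#'   `treatment` (`"control"`/`"warmed"`), `layer`, `temperature`, `moisture`.
#' @param growing_season_only restrict to May-October (the heater-active
#'   window used for profile summaries)?
#' @return data.frame, one row per layer: `layer`, `delta_temperature`,
#'   `delta_temperature_se`, `delta_moisture`, `delta_moisture_se`,
#'   `n_years`.
#' @export
treatment_profile <- function(records, growing_season_only = TRUE) {
  need <- c("year", "doy", "treatment", "layer", "temperature", "moisture")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (growing_season_only)
    records <- records[doy_in_growing_season(records$doy), , drop = FALSE]
  out <- list()
  for (ly in unique(records$layer)) {
    sub <- records[records$layer == ly, , drop = FALSE]
    if (length(unique(sub$treatment)) < 2L) {
      message("layer '", ly, "' lacks one treatment; skipped")
      next
    }
    # annual treatment means, then per-year differences
    ann <- aggregate(cbind(temperature, moisture) ~ year + treatment,
                     data = sub, FUN = mean)
    w <- ann[ann$treatment == "warmed", ]
    c_ <- ann[ann$treatment == "control", ]
    yrs <- intersect(w$year, c_$year)
    dT <- w$temperature[match(yrs, w$year)] - c_$temperature[match(yrs, c_$year)]
    dM <- w$moisture[match(yrs, w$year)] - c_$moisture[match(yrs, c_$year)]
    se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
    out[[ly]] <- data.frame(
      layer = ly,
      delta_temperature = mean(dT), delta_temperature_se = se(dT),
      delta_moisture = mean(dM), delta_moisture_se = se(dM),
      n_years = length(yrs)
    )
  }
  if (!length(out)) stop("no layer had both treatments")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
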