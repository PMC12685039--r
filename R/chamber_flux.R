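#' Quality-control settings for flux estimation
#'
#' @param min_r2 optional minimum R2 of the concentration regression; fluxes
#'   below it are flagged (`NULL` disables the check, the default).
#' @param spike_mad samples whose absolute deviation from the window median
#'   exceeds `spike_mad` times the window MAD are dropped as spikes.
#' @param min_samples minimum number of regression-window samples; fewer
#'   yields a flagged record with no flux.
#' @return object of class `flux_qc`.
#' @export
flux_qc <- function(min_r2 = NULL, spike_mad = 5, min_samples = 4L) {
  structure(list(min_r2 = min_r2, spike_mad = spike_mad,
                 min_samples = as.integer(min_samples)), class = "flux_qc")
}

#' Estimate a flux from one chamber closure
#'
#' Hybrid accumulation + dynamic estimator for a vented chamber:
#'
#' `Flux = (dC/dt * V/A + (C_out - C_in) * Q/A) * M/V0 * P/P0 * T0/T`
#'
#' where `dC/dt` is the ordinary-least-squares slope of the concentration
#' series over the species-specific regression window (minutes 5-10 for NO,
#' 5-20 for N2O), `C_out` is the mean chamber concentration over that window,
#' and `C_in` the ambient concentration from the post-opening window. The
#' accumulation term captures headspace build-up; the dynamic term corrects
#' for chamber air withdrawn by the analyzer and replaced by ambient makeup
#' air. Concentrations are dry mole fractions (nmol mol-1) and the final
#' factor converts to ug N m-2 h-1 at chamber temperature and pressure; set
#' `units = "ug_m3"` if the series is already in mass-concentration units.
#'
#' @param closure a `closure_series` (see [simulate_closure()] or
#'   [read_closures()]).
#' @param qc a [flux_qc()].
#' @param units `"nmol_mol"` (default) or `"ug_m3"`.
#' @return a one-row data.frame of class `flux_record`: `species`, `flux`,
#'   `slope` (nmol mol-1 h-1), `slope_r2`, `accumulation_term`,
#'   `dynamic_term` (all ug N m-2 h-1), ids, `n_samples`, `qc_flags`. The
#'   flux always equals accumulation + dynamic term.
#' @export
compute_flux <- function(closure, qc = flux_qc(), units = c("nmol_mol", "ug_m3")) {
  stopifnot(inherits(closure, "closure_series"))
  units <- match.arg(units)
  s <- closure$samples
  if (any(!is.finite(s$conc)))
    stop("non-finite concentrations in closure series")
  if (is.unsorted(s$t_s, strictly = TRUE))
    stop("samples must be strictly time-ordered")
  geom <- closure$geometry
  window <- regression_window(closure$species)
  inwin <- s$phase == "closure" & s$t_s >= window[1] & s$t_s <= window[2]
  win <- s[inwin, , drop = FALSE]

  flags <- character(0)
  if (!is.null(qc$spike_mad) && nrow(win) >= qc$min_samples) {
    m <- median(win$conc)
    dev <- abs(win$conc - m)
    madv <- mad(win$conc)
    if (madv > 0) {
      spikes <- dev > qc$spike_mad * madv
      if (any(spikes)) {
        flags <- c(flags, sprintf("spikes_removed:%d", sum(spikes)))
        win <- win[!spikes, , drop = FALSE]
      }
    }
  }

  rec <- data.frame(
    species = closure$species, flux = NA_real_, slope = NA_real_,
    slope_r2 = NA_real_, accumulation_term = NA_real_,
    dynamic_term = NA_real_, chamber_id = closure$chamber_id,
    plot_id = closure$plot_id, treatment = closure$treatment,
    n_samples = nrow(win), qc_flags = "", stringsAsFactors = FALSE
  )
  if (nrow(win) < qc$min_samples) {
    rec$qc_flags <- paste(c(flags, "too_few_samples"), collapse = ";")
    class(rec) <- c("flux_record", "data.frame")
    return(rec)
  }

  if (var(win$conc) == 0) {
    slope <- 0                            # constant window: exactly zero
    r2 <- NA_real_
  } else {
    fit <- lm(conc ~ I(t_s / 3600), data = win)
    slope <- coef(fit)[[2]]               # nmol mol-1 h-1 (or ug m-3 h-1)
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((win$conc - mean(win$conc))^2)
  }
  c_out <- mean(win$conc)
  c_in <- closure$ambient_C
  f <- if (units == "nmol_mol")
    conc_conversion(closure$species, closure$T_K, closure$P_hPa) else 1
  acc <- slope * geom$V / geom$A * f
  dyn <- (c_out - c_in) * geom$Q / geom$A * f
  if (!is.null(qc$min_r2) && !is.na(r2) && r2 < qc$min_r2)
    flags <- c(flags, "low_r2")

  rec$flux <- acc + dyn
  rec$slope <- slope
  rec$slope_r2 <- r2
  rec$accumulation_term <- acc
  rec$dynamic_term <- dyn
  rec$qc_flags <- paste(flags, collapse = ";")
  class(rec) <- c("flux_record", "data.frame")
  rec
}

#' Aggregate chamber fluxes to daily treatment means
#'
#' Per treatment, species and day: the treatment mean is the mean over
#' chambers of chamber means (equal chamber weighting, balancing unequal
#' closure counts), and the SE is taken across chamber means. Note the
#' chambers are nested in plots, so this SE describes chamber-scale spread,
#' not fully independent replication. QC-flagged records (those with a flux
#' or with `too_few_samples`) are excluded and counted.
#'
#' @param records data.frame of flux records: columns `treatment`, `species`,
#'   `year`, `doy`, `chamber_id`, `flux`, and optionally `qc_flags`.
#' @param drop_flagged exclude records whose `qc_flags` is non-empty?
#' @return data.frame `daily_flux`: `year`, `doy`, `treatment`, `species`,
#'   `mean_flux`, `se`, `n_fluxes`, `n_chambers`, `n_excluded`.
#' @export
daily_aggregate <- function(records, drop_flagged = TRUE) {
  need <- c("treatment", "species", "year", "doy", "chamber_id", "flux")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(records$species)) > 1L &&
      !all(c("NO", "N2O") %in% unique(records$species)))
    stop("unknown species in records")
  bad <- is.na(records$flux)
  if (drop_flagged && "qc_flags" %in% names(records))
    bad <- bad | nzchar(records$qc_flags)
  excl <- records[bad, , drop = FALSE]
  keep <- records[!bad, , drop = FALSE]
  if (!nrow(keep)) {
    message("no QC-passing fluxes; empty aggregate")
    return(data.frame(year = integer(0), doy = integer(0),
                      treatment = character(0), species = character(0),
                      mean_flux = numeric(0), se = numeric(0),
                      n_fluxes = integer(0), n_chambers = integer(0),
                      n_excluded = integer(0)))
  }
  ch <- aggregate(flux ~ year + doy + treatment + species + chamber_id,
                  data = keep, FUN = mean)
  nf <- aggregate(flux ~ year + doy + treatment + species, data = keep,
                  FUN = length)
  names(nf)[names(nf) == "flux"] <- "n_fluxes"
  day <- aggregate(flux ~ year + doy + treatment + species, data = ch,
                   FUN = function(x) c(
                     mean = mean(x),
                     se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
                     n = length(x)))
  day <- cbind(day[c("year", "doy", "treatment", "species")],
               as.data.frame(day$flux))
  names(day) <- c("year", "doy", "treatment", "species",
                  "mean_flux", "se", "n_chambers")
  day <- merge(day, nf, by = c("year", "doy", "treatment", "species"))
  nx <- if (nrow(excl))
    aggregate(flux ~ year + doy + treatment + species, data = excl,
              FUN = length, na.action = stats::na.pass)
  else NULL
  if (!is.null(nx)) {
    names(nx)[names(nx) == "flux"] <- "n_excluded"
    day <- merge(day, nx, all.x = TRUE)
    day$n_excluded[is.na(day$n_excluded)] <- 0L
  } else day$n_excluded <- 0L
  day$n_chambers <- as.integer(day$n_chambers)
  day <- day[order(day$species, day$treatment, day$year, day$doy), ]
  rownames(day) <- NULL
  day
}

#' Integrate daily fluxes over a period
#'
#' Cumulative flux (kg N ha-1) over a day-of-year window within one or more
#' years: each day contributes its 24-h mean (1 ug N m-2 h-1 over one day =
#' 2.4e-4 kg N ha-1); interior missing days are filled by linear
#' interpolation up to `max_gap` days, beyond which the value is flagged and
#' the coverage fraction reported. Under the default snow policy
#' (`snow_policy = "no_winter_zero"`), NO fluxes contribute zero from
#' December 1 to March 31, the snow-cover assumption used for annual NO
#' totals; `"none"` integrates everything as observed.
#'
#' @param daily a `daily_flux` table from [daily_aggregate()] (one treatment
#'   and species, or the table is split internally).
#' @param period length-2 day-of-year window `c(start, end)` (inclusive);
#'   default the whole year.
#' @param years years to include (default: all present); each year is
#'   integrated and summed.
#' @param snow_policy `"no_winter_zero"` (default) or `"none"`.
#' @param max_gap largest interior gap (days) filled by interpolation.
#' @param label period label carried to the output.
#' @return data.frame `cumulative_flux`: `period`, `treatment`, `species`,
#'   `kg_n_ha`, `coverage`, `flag` (one row per treatment x species).
#' @export
cumulative_flux <- function(daily, period = c(1L, 365L), years = NULL,
                            snow_policy = c("no_winter_zero", "none"),
                            max_gap = 7L, label = NULL) {
  snow_policy <- match.arg(snow_policy)
  if (period[2] < period[1]) stop("period end precedes start")
  if (!nrow(daily)) stop("empty period: no daily fluxes supplied")
  if (is.null(years)) years <- sort(unique(daily$year))
  if (is.null(label))
    label <- sprintf("doy %d-%d, years %s", period[1], period[2],
                     paste(range(years), collapse = "-"))
  combos <- unique(daily[c("treatment", "species")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$treatment[i]; sp <- combos$species[i]
    total <- 0; n_have <- 0; n_days <- 0; flag <- ""
    for (yr in years) {
      sub <- daily[daily$treatment == tr & daily$species == sp &
                     daily$year == yr &
                     daily$doy >= period[1] & daily$doy <= period[2], ]
      doys <- period[1]:period[2]
      n_days <- n_days + length(doys)
      if (!nrow(sub)) next
      vals <- approx(sub$doy, sub$mean_flux, xout = doys, rule = 2)$y
      have <- doys %in% sub$doy
      n_have <- n_have + sum(have)
      gaps <- rle(!have)
      if (any(gaps$lengths[gaps$values] > max_gap))
        flag <- "gap_exceeds_cap"
      if (sp == "NO" && snow_policy == "no_winter_zero")
        vals[doy_in_snow_window(doys)] <- 0
      total <- total + sum(vals) * KG_HA_PER_UG_M2_DAY
    }
    if (n_have == 0) stop("empty period for ", tr, "/", sp)
    data.frame(period = label, treatment = tr, species = sp,
               kg_n_ha = total, coverage = n_have / n_days, flag = flag)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default season calendar
#'
#' Growing season May 1 - Oct 31 (day-of-year 121-304) and dormant season
#' Nov 1 - Apr 30, the plant phenology split used throughout.
#'
#' @return named list of `c(start_doy, end_doy)` windows; the dormant season
#'   is split into its two within-year segments.
#' @export
season_calendar <- function() {
  list(growing = c(121L, 304L),
       dormant_fall = c(305L, 365L),
       dormant_spring = c(1L, 120L))
}

#' Partition cumulative flux by season
#'
#' Integrates each season window of `calendar` separately (same integration
#' and snow policy as [cumulative_flux()]) and reports each season's share.
#' The windows must not overlap; together with exhaustive windows the season
#' totals sum to the full-period value.
#'
#' @inheritParams cumulative_flux
#' @param calendar named list of day-of-year windows, e.g.
#'   [season_calendar()].
#' @return data.frame with one row per season x treatment x species:
#'   `season`, `treatment`, `species`, `kg_n_ha`, `share`.
#' @export
seasonal_partition <- function(daily, calendar = season_calendar(),
                               years = NULL,
                               snow_policy = c("no_winter_zero", "none"),
                               max_gap = 7L) {
  snow_policy <- match.arg(snow_policy)
  wins <- calendar
  cover <- unlist(lapply(wins, function(w) w[1]:w[2]))
  if (anyDuplicated(cover)) stop("season windows overlap")
  parts <- lapply(names(wins), function(nm) {
    cf <- cumulative_flux(daily, period = wins[[nm]], years = years,
                          snow_policy = snow_policy, max_gap = max_gap,
                          label = nm)
    cf$season <- nm
    cf
  })
  res <- do.call(rbind, parts)
  tot <- aggregate(kg_n_ha ~ treatment + species, data = res, FUN = sum)
  names(tot)[names(tot) == "kg_n_ha"] <- "total"
  res <- merge(res, tot, by = c("treatment", "species"))
  res$share <- res$kg_n_ha / res$total
  res <- res[c("season", "treatment", "species", "kg_n_ha", "share")]
  res[order(res$species, res$treatment), ]
}
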