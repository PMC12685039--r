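#' Moisture-based N2:N2O scaling model
#'
#' Linear dependence of the denitrification product ratio N2:N2O on soil
#' moisture: `ratio = slope * WFPS - intercept`, clamped at zero (the ratio
#' root sits near WFPS = intercept/slope ~ 8.5 %). Default coefficients come
#' from a 15N-tracer calibration (`ratio = 0.13 WFPS - 1.10`). Temperature
#' is deliberately absent: the calibration incubations showed no significant
#' temperature effect on the ratio, so the model is structurally
#' moisture-only. The `validity` range records the WFPS domain over which
#' the calibration holds; evaluating outside it warns but proceeds.
#'
#' @param slope per % WFPS (> 0).
#' @param intercept dimensionless.
#' @param validity WFPS range (%) over which the ratio model is applied
#'   without warning; defaults to the span of field WFPS observations.
#' @return object of class `n2_scaling_model`.
#' @export
n2_scaling_model <- function(slope = 0.13, intercept = 1.10,
                             validity = c(9, 100)) {
  if (slope <= 0) stop("slope must be positive")
  structure(list(slope = slope, intercept = intercept, validity = validity),
            class = "n2_scaling_model")
}

#' Estimate N2 flux from N2O flux and soil moisture
#'
#' `N2 = max(0, slope * WFPS - intercept) * N2O`. Days with negative N2O
#' flux (chamber uptake) are returned as missing with a flag rather than as
#' a negative N2 efflux, which would be non-physical for denitrification.
#'
#' @param n2o_flux N2O flux (ug N m-2 h-1).
#' @param wfps WFPS (%), in `[0, 100]`.
#' @param model an [n2_scaling_model()].
#' @return data.frame: `n2_flux` (ug N m-2 h-1), `ratio`, `flag`.
#' @export
estimate_n2 <- function(n2o_flux, wfps, model = n2_scaling_model()) {
  if (any(wfps < 0 | wfps > 100, na.rm = TRUE))
    stop("wfps must lie in [0, 100]")
  if (any(wfps < model$validity[1] | wfps > model$validity[2], na.rm = TRUE))
    warning("WFPS outside the scaling model's calibration range")
  ratio <- pmax(model$slope * wfps - model$intercept, 0)
  neg <- !is.na(n2o_flux) & n2o_flux < 0
  n2 <- ifelse(neg, NA_real_, ratio * n2o_flux)
  data.frame(n2_flux = n2, ratio = ratio,
             flag = ifelse(neg, "negative_n2o", ""))
}

#' Growing-season cumulative N2 flux
#'
#' Applies [estimate_n2()] to a daily N2O series aligned with daily WFPS and
#' integrates the resulting N2 series over the growing season (the scaled N2
#' estimate is a growing-season quantity; the ratio calibration does not
#' extend to frozen soil). Missing-day handling follows [cumulative_flux()].
#'
#' @param daily_n2o `daily_flux` table for species N2O (per treatment).
#' @param soil_daily data.frame with `year`, `doy`, `treatment`, `wfps`
#'   (treatment-level daily means).
#' @param model an [n2_scaling_model()].
#' @param season day-of-year window; default the growing season.
#' @param max_gap interpolation cap (days).
#' @return `cumulative_flux`-style data.frame with species `"N2"`.
#' @export
seasonal_n2 <- function(daily_n2o, soil_daily, model = n2_scaling_model(),
                        season = season_calendar()$growing, max_gap = 7L) {
  d <- merge(daily_n2o[daily_n2o$species == "N2O", ],
             soil_daily[c("year", "doy", "treatment", "wfps")],
             by = c("year", "doy", "treatment"))
  if (!nrow(d)) stop("no aligned N2O/WFPS days")
  est <- estimate_n2(d$mean_flux, d$wfps, model)
  d$mean_flux <- est$n2_flux
  d$species <- "N2"
  d <- d[!is.na(d$mean_flux), ]
  cumulative_flux(d, period = season, snow_policy = "none",
                  max_gap = max_gap, label = "growing_season")
}

#' Net N mineralization and nitrification rates from an incubation
#'
#' `R_M = ((NH4_after + NO3_after) - (NH4_before + NO3_before)) / days` and
#' `R_N = (NO3_after - NO3_before) / days` (mg N kg-1 d-1). Net rates may be
#' negative (consumption exceeding production) and are not clipped.
#'
#' @param rec data.frame with columns `nh4_before`, `no3_before`,
#'   `nh4_after`, `no3_after`, `days`, plus any id columns, which are
#'   carried through.
#' @return the input with appended columns `r_miner` and `r_nitr`.
#' @export
net_rates <- function(rec) {
  need <- c("nh4_before", "no3_before", "nh4_after", "no3_after", "days")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(rec$days <= 0)) stop("incubation duration must be positive")
  rec$r_miner <- ((rec$nh4_after + rec$no3_after) -
                    (rec$nh4_before + rec$no3_before)) / rec$days
  rec$r_nitr <- (rec$no3_after - rec$no3_before) / rec$days
  rec
}

#' Fit an Arrhenius-form temperature dependence to incubation rates
#'
#' Least squares of `R = a * exp(b * T)` over the incubation temperature
#' gradient, initialized from the log-linear regression of positive rates.
#' This is the same functional form as the flux temperature response but
#' confined to laboratory rate extrapolation.
#'
#' @param temp_C incubation temperatures (degrees C), at least 3 distinct.
#' @param rate rates (mg N kg-1 d-1), positive values needed to initialize.
#' @return object of class `arrhenius_fit`: `a`, `b`, `r2`, `temp_range`.
#' @export
fit_arrhenius <- function(temp_C, rate) {
  ok <- is.finite(temp_C) & is.finite(rate)
  temp_C <- temp_C[ok]; rate <- rate[ok]
  if (length(unique(temp_C)) < 3L)
    stop("need at least 3 distinct temperatures")
  pos <- rate > 0
  if (sum(pos) < 2L) stop("need positive rates to initialize")
  if (var(rate) < 1e-14 * max(mean(rate)^2, 1)) {
    pars <- c(a = mean(rate), b = 0)
    fitted_y <- rep(mean(rate), length(rate))
  } else {
    init <- lm(log(rate[pos]) ~ temp_C[pos])
    fit <- fit_exponential_ls(
      data.frame(x = temp_C, y = rate, w = 1),
      list(A = exp(coef(init)[[1]]), k = coef(init)[[2]]))
    pars <- c(a = coef(fit)[["A"]], b = coef(fit)[["k"]])
    fitted_y <- predict(fit)
  }
  ss_res <- sum((rate - fitted_y)^2)
  ss_tot <- sum((rate - mean(rate))^2)
  structure(list(
    a = unname(pars[["a"]]), b = unname(pars[["b"]]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    temp_range = range(temp_C)
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> R = %.3g * exp(%.4f T); Q10 = %.2f, R2 = %.3f\n",
              x$a, x$b, exp(10 * x$b), x$r2))
  invisible(x)
}

#' Predict a rate at a query temperature
#'
#' Evaluates `a * exp(b * T)`; querying more than `guard` degrees C beyond
#' the fitted range triggers an extrapolation warning but still returns the
#' value.
#'
#' @param fit an [fit_arrhenius()] result.
#' @param temperature query temperature (degrees C).
#' @param guard extrapolation guard band (degrees C).
#' @return predicted rate.
#' @export
predict_rate <- function(fit, temperature, guard = 5) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  lo <- fit$temp_range[1] - guard
  hi <- fit$temp_range[2] + guard
  if (any(temperature < lo | temperature > hi))
    warning("temperature outside the fitted range + guard band; extrapolating")
  fit$a * exp(fit$b * temperature)
}
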