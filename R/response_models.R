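# Levenberg-Marquardt least squares for y = A * exp(k x) (weights w),
# falling back to Gauss-Newton nls when minpack.lm is unavailable.
# Convergence tolerance 1e-10 on the parameters.
fit_exponential_ls <- function(df, start) {
  if (requireNamespace("minpack.lm", quietly = TRUE)) {
    minpack.lm::nlsLM(y ~ A * exp(k * x), data = df, start = start,
                      weights = df$w,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-10))
  } else {
    nls(y ~ A * exp(k * x), data = df, start = start, weights = df$w,
        control = stats::nls.control(maxiter = 500, tol = 1e-8,
                                     minFactor = 1e-14, warnOnly = FALSE))
  }
}

#' Bin fluxes against soil temperature or moisture
#'
#' Joins daily fluxes to same-day soil state and averages them within
#' left-closed, right-open bins of the chosen variable (0.5 degrees C for
#' temperature, 1 % for WFPS are the conventional widths). Binning before
#' fitting reduces the leverage of the dense mid-range and is how the
#' response curves are estimated throughout.
#'
#' @param data data.frame with a flux column and the binning variable; e.g.
#'   a `daily_flux` table merged with daily soil state.
#' @param variable `"temperature"` or `"wfps"`.
#' @param width bin width (0.5 degrees C or 1 % WFPS by default).
#' @param flux_col,var_col column names holding the flux and the variable;
#'   `var_col` defaults to `"temp_mineral"` for temperature and `"wfps"` for
#'   moisture.
#' @param season optional `c(start_doy, end_doy)` day-of-year filter (needs
#'   a `doy` column); e.g. `season_calendar()$growing`.
#' @return data.frame of class `binned_flux`: `bin_center`, `bin_width`,
#'   `mean_flux`, `n`.
#' @export
bin_fluxes <- function(data, variable = c("temperature", "wfps"),
                       width = NULL, flux_col = "mean_flux",
                       var_col = NULL, season = NULL) {
  variable <- match.arg(variable)
  if (is.null(width)) width <- if (variable == "temperature") 0.5 else 1
  if (width <= 0) stop("width must be positive")
  if (is.null(var_col))
    var_col <- if (variable == "temperature") "temp_mineral" else "wfps"
  if (!is.null(season)) {
    if (!"doy" %in% names(data)) stop("season filter needs a doy column")
    data <- data[data$doy >= season[1] & data$doy <= season[2], , drop = FALSE]
  }
  x <- data[[var_col]]
  y <- data[[flux_col]]
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("no matched flux/soil-state records to bin")
  x <- x[ok]; y <- y[ok]
  idx <- floor(x / width)                       # left-closed, right-open
  mean_flux <- tapply(y, idx, mean)
  n <- tapply(y, idx, length)
  res <- data.frame(
    bin_center = (as.numeric(names(mean_flux)) + 0.5) * width,
    bin_width = width,
    mean_flux = as.numeric(mean_flux),
    n = as.integer(n)
  )
  res <- res[order(res$bin_center), ]
  rownames(res) <- NULL
  attr(res, "variable") <- variable
  class(res) <- c("binned_flux", "data.frame")
  res
}

#' Fit an exponential temperature response and apparent Q10
#'
#' Nonlinear least squares of `F = A * exp(k * T)` on bin means, initialized
#' from the log-linear regression of the positive bins. The apparent
#' temperature sensitivity is `Q10 = exp(10 k)`. R2 is computed on the bin
#' means. Bins with non-positive means are excluded from the initialization
#' only, not from the fit.
#'
#' @param bins a `binned_flux` table (temperature bins) or any data.frame
#'   with `bin_center` and `mean_flux`; at least 5 bins spanning at least
#'   5 degrees C.
#' @param weights `"equal"` (bins weighted equally, as plotted; default) or
#'   `"n"` (bins weighted by observation count).
#' @return object of class `temp_response_fit`: `A`, `k`, `q10`, `r2`,
#'   `n_bins`, `temp_range`, `bins`.
#' @export
fit_temperature_response <- function(bins, weights = c("equal", "n")) {
  weights <- match.arg(weights)
  x <- bins$bin_center
  y <- bins$mean_flux
  if (length(x) < 5L) stop("need at least 5 bins")
  if (diff(range(x)) < 5) stop("bins must span at least 5 degrees C")
  pos <- y > 0
  if (sum(pos) < 2L) stop("need positive mean fluxes to initialize the fit")
  init <- lm(log(y[pos]) ~ x[pos])
  start <- list(A = exp(coef(init)[[1]]), k = coef(init)[[2]])
  w <- if (weights == "n" && "n" %in% names(bins)) bins$n else rep(1, length(x))
  df <- data.frame(x = x, y = y, w = w)
  fit <- tryCatch(fit_exponential_ls(df, start), error = function(e) e)
  if (inherits(fit, "error")) {
    # constant data has k ~ 0; nls cannot move, fall back to the exact LS
    # solution of the degenerate case, otherwise surface the initializer
    if (var(y) < 1e-12 * max(mean(y)^2, 1)) {
      pars <- c(A = mean(y), k = 0)
      fitted_y <- rep(mean(y), length(y))
    } else {
      stop("temperature-response fit did not converge; log-linear start: A=",
           signif(start$A, 4), ", k=", signif(start$k, 4))
    }
  } else {
    pars <- coef(fit)
    fitted_y <- predict(fit)
  }
  ss_res <- sum(w * (y - fitted_y)^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    A = unname(pars[["A"]]), k = unname(pars[["k"]]),
    q10 = q10_from_k(unname(pars[["k"]])),
    r2 = max(min(r2, 1), 0), n_bins = length(x), temp_range = range(x),
    bins = as.data.frame(bins)
  ), class = "temp_response_fit")
}

#' @export
print.temp_response_fit <- function(x, ...) {
  cat(sprintf(
    "<temp_response_fit> F = %.3g * exp(%.4f T); Q10 = %.2f, R2 = %.2f (%d bins, %.1f-%.1f C)\n",
    x$A, x$k, x$q10, x$r2, x$n_bins, x$temp_range[1], x$temp_range[2]))
  invisible(x)
}

#' Apparent Q10 from an exponential temperature coefficient
#'
#' `Q10 = exp(10 k)`: the factor by which flux increases per 10 degrees C
#' under `F = A exp(k T)`.
#'
#' @param k temperature coefficient (per degree C), finite.
#' @return Q10 (dimensionless).
#' @export
q10_from_k <- function(k) {
  if (any(!is.finite(k))) stop("k must be finite")
  exp(10 * k)
}

#' Fit a quadratic moisture response
#'
#' Least-squares quadratic `F = c2 W^2 + c1 W + c0` on WFPS bin means. The
#' optimum WFPS `-c1 / (2 c2)` is reported only when the curvature is
#' negative and the vertex lies inside the fitted moisture range.
#'
#' @param bins a `binned_flux` table (WFPS bins) with at least 6 bins.
#' @return object of class `moisture_response_fit`: `c2`, `c1`, `c0`,
#'   `optimum` (NA when not admissible), `r2`, `wfps_range`, `bins`.
#' @export
fit_moisture_response <- function(bins) {
  x <- bins$bin_center
  y <- bins$mean_flux
  if (length(x) < 6L) stop("need at least 6 bins")
  if (var(x) == 0) stop("degenerate design: all bins at the same WFPS")
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  c0 <- cf[[1]]; c1 <- cf[[2]]; c2 <- cf[[3]]
  vertex <- -c1 / (2 * c2)
  admissible <- is.finite(vertex) && c2 < 0 &&
    vertex >= min(x) && vertex <= max(x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(
    c2 = c2, c1 = c1, c0 = c0,
    optimum = if (admissible) vertex else NA_real_,
    r2 = r2,
    wfps_range = range(x), bins = as.data.frame(bins)
  ), class = "moisture_response_fit")
}

#' @export
print.moisture_response_fit <- function(x, ...) {
  cat(sprintf("<moisture_response_fit> c2 = %.3g; optimum %s %% WFPS; R2 = %.2f\n",
              x$c2,
              if (is.na(x$optimum)) "not admissible" else sprintf("%.1f", x$optimum),
              x$r2))
  invisible(x)
}

#' Q10-expected counterfactual flux under warming
#'
#' The flux a purely temperature-driven response would predict after a
#' `delta_T` warming: `F_expected = F_control * q10^(delta_T / 10)`. Works at
#' any granularity (chamber, day, cumulative value).
#'
#' @param control_flux control flux (any units).
#' @param q10 apparent temperature sensitivity (> 0).
#' @param delta_T warming magnitude (degrees C).
#' @return expected flux under warming, same units as `control_flux`.
#' @export
q10_expected_flux <- function(control_flux, q10, delta_T) {
  if (any(q10 <= 0)) stop("q10 must be positive")
  control_flux * q10^(delta_T / 10)
}

#' Observed vs Q10-expected warming response
#'
#' Compares the observed warming response with the counterfactual expectation
#' from the temperature response alone: expected increase
#' `(q10^(dT/10) - 1) * 100` %, observed change `(warmed/control - 1) * 100`
#' %, and the shortfall of the warmed flux relative to the expected flux,
#' `(warmed / expected - 1) * 100` %.
#'
#' @param control,warmed matched-period fluxes (control must be non-zero).
#' @param q10 apparent temperature sensitivity.
#' @param delta_T realized warming (degrees C).
#' @return data.frame: `expected_increase_pct`, `observed_change_pct`,
#'   `shortfall_pct`.
#' @export
expected_vs_observed <- function(control, warmed, q10, delta_T) {
  if (any(control == 0)) stop("zero control flux")
  fac <- q10^(delta_T / 10)
  obs <- warmed / control
  data.frame(
    expected_increase_pct = (fac - 1) * 100,
    observed_change_pct = (obs - 1) * 100,
    shortfall_pct = (obs / fac - 1) * 100
  )
}
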