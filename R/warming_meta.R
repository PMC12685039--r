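#' Log response ratio (effect size)
#'
#' `lnRR = ln(x_w) - ln(x_c)`, the standard effect size for manipulation
#' experiments. Non-positive inputs cannot be log-transformed and return
#' `NA` (the log-transform guard), not an error.
#'
#' @param x_w,x_c treatment (warmed) and control means.
#' @return lnRR, `NA` where either mean is non-positive.
#' @export
lnrr <- function(x_w, x_c) {
  bad <- !is.na(x_w) & !is.na(x_c) & (x_w <= 0 | x_c <= 0)
  out <- log(ifelse(bad, NA_real_, x_w)) - log(ifelse(bad, NA_real_, x_c))
  if (any(bad)) attr(out, "flag") <- "non_positive_input"
  out
}

#' Warming response ratio standardized to 1 degree C
#'
#' `RRn = ((x_w - x_c) / x_c) / delta_T`, making studies with different
#' warming magnitudes comparable.
#'
#' @param x_w,x_c treatment and control means (`x_c` non-zero).
#' @param delta_T realized warming (degrees C, > 0).
#' @return RRn per degree C.
#' @export
rrn <- function(x_w, x_c, delta_T) {
  if (any(delta_T <= 0)) stop("delta_T must be positive")
  if (any(x_c == 0, na.rm = TRUE)) stop("control mean must be non-zero")
  ((x_w - x_c) / x_c) / delta_T
}

#' Effect sizes for paired warmed/control samples
#'
#' Per variable, the mean relative effect `(warmed - control) / control`
#' across sampling times, its seeded bootstrap SE (resampling sampling
#' times), and the mean lnRR alongside. Variables present in only one
#' treatment column pattern are skipped with a message.
#'
#' @param pairs data.frame with columns `variable`, `control`, `warmed`
#'   (one row per variable x sampling time).
#' @param n_boot bootstrap resamples for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame of class `effect_size`: `variable`, `x_w`, `x_c`,
#'   `relative_effect_pct`, `se_pct`, `lnrr`, `n`.
#' @export
effect_table <- function(pairs, n_boot = 1000L, seed = 1L) {
  need <- c("variable", "control", "warmed")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  set.seed(seed)
  out <- list()
  for (v in unique(pairs$variable)) {
    sub <- pairs[pairs$variable == v, ]
    ok <- complete.cases(sub[c("control", "warmed")])
    sub <- sub[ok, ]
    if (!nrow(sub)) {
      message("variable '", v, "' has no complete pairs; skipped")
      next
    }
    rel <- (sub$warmed - sub$control) / sub$control * 100
    n <- nrow(sub)
    se <- if (n > 1L) {
      boots <- vapply(seq_len(n_boot), function(i)
        mean(rel[sample.int(n, n, replace = TRUE)]), numeric(1))
      sd(boots)
    } else NA_real_
    out[[v]] <- data.frame(
      variable = v, x_w = mean(sub$warmed), x_c = mean(sub$control),
      relative_effect_pct = mean(rel), se_pct = se,
      lnrr = mean(lnrr(sub$warmed, sub$control), na.rm = TRUE), n = n
    )
  }
  if (!length(out)) stop("no variable had paired observations")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("effect_size", "data.frame")
  res
}

#' Cross-study regression of N2O warming response on moisture change
#'
#' Ordinary least squares of the per-degree warming response of N2O
#' emissions (RRn, computed from each site's control and warmed means and
#' its warming magnitude) on the warming-induced WFPS change. This is an
#' unweighted cross-site regression, not a variance-weighted meta-analysis.
#'
#' @param studies data.frame with one row per site and columns
#'   `n2o_control`, `n2o_warmed`, `delta_t`, `delta_wfps_pct` (plus any
#'   covariates, echoed into the result for provenance). Alternatively a
#'   precomputed `rrn` column is used as the response.
#' @param predictor name of the predictor column (default
#'   `"delta_wfps_pct"`; percent units — fractional units rescale the slope
#'   exactly and leave R2 unchanged).
#' @return object of class `meta_regression`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`, `predictor`, `studies` (the table with the computed
#'   `rrn` column).
#' @export
meta_regression <- function(studies, predictor = "delta_wfps_pct") {
  if (!predictor %in% names(studies))
    stop("predictor column '", predictor, "' not found")
  if (!"rrn" %in% names(studies)) {
    need <- c("n2o_control", "n2o_warmed", "delta_t")
    miss <- setdiff(need, names(studies))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    studies$rrn <- rrn(studies$n2o_warmed, studies$n2o_control,
                       studies$delta_t)
  }
  ok <- is.finite(studies$rrn) & is.finite(studies[[predictor]])
  use <- studies[ok, ]
  if (nrow(use) < 4L) stop("need at least 4 usable studies")
  if (var(use[[predictor]]) == 0)
    stop("degenerate design: predictor is constant")
  fit <- lm(as.formula(paste("rrn ~", predictor)), data = use)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((use$rrn - mean(use$rrn))^2)
  r2 <- 1 - ss_res / ss_tot
  # slope t-test by hand: summary.lm warns on exact fits
  se_b <- sqrt(ss_res / (nrow(use) - 2) /
                 sum((use[[predictor]] - mean(use[[predictor]]))^2))
  tval <- coef(fit)[[2]] / se_b
  p <- 2 * pt(abs(tval), df = nrow(use) - 2, lower.tail = FALSE)
  structure(list(
    slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
    r2 = r2, p_value = p,
    n = nrow(use), predictor = predictor, studies = use
  ), class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf(
    "<meta_regression> RRn = %.4f + %.4f * %s; R2 = %.2f, p = %.3g (n = %d sites)\n",
    x$intercept, x$slope, x$predictor, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Synthetic cross-study site table
#'
#' A deterministic 10-site stand-in for a cross-study synthesis of forest
#' soil-warming N2O experiments. It is synthetic: no field study is
#' represented. It is calibrated to the published cross-study summary
#' pattern — the per-degree N2O response (RRn) increases with the
#' warming-induced WFPS change with R2 = 0.45, and moisture losses
#' concentrate at sites with mean annual precipitation below ~1,000 mm. The
#' residuals are constructed orthogonal to the predictor and scaled so that
#' an OLS fit of RRn on dWFPS recomputes exactly that R2 from the stored
#' N2O means. Shipped also as `inst/extdata/site_table_synthetic.csv`.
#'
#' @param r2 coefficient of determination to embed.
#' @param slope,intercept linear relation of RRn (per degree C) to the WFPS
#'   change (%).
#' @return data.frame with columns `site_id`, `mat_C`, `map_mm`, `ndep`,
#'   `ph`, `soc`, `cn`, `bd`, `soil_temp`, `delta_t`, `wfps`,
#'   `delta_wfps_pct`, `n2o_control`, `n2o_warmed`.
#' @export
synthetic_site_table <- function(r2 = 0.45, slope = 0.012, intercept = 0.02) {
  dw <- c(-18, -15, -12, -9, -6, -4, -2, 0, 3, 6)
  hat <- intercept + slope * dw
  # alternating pattern projected orthogonal to [1, dw], scaled to the R2
  r0 <- rep(c(1, -1), 5)
  X <- cbind(1, dw)
  r0 <- r0 - X %*% solve(crossprod(X), crossprod(X, r0))
  ssr <- sum((hat - mean(hat))^2)
  res <- drop(r0) * sqrt(ssr * (1 - r2) / r2 / sum(r0^2))
  rrn_val <- hat + res
  delta_t <- c(2, 1.5, 3, 2, 4, 2.5, 1, 2, 3.5, 2)
  n2o_control <- c(0.9, 1.4, 0.6, 2.1, 1.1, 0.8, 1.6, 1.0, 1.3, 0.7)
  data.frame(
    site_id = sprintf("SYN%02d", 1:10),
    mat_C = c(3.5, 5.2, 2.1, 7.8, 4.4, 6.1, 8.9, 4.5, 9.6, 6.8),
    map_mm = c(620, 710, 540, 860, 790, 900, 980, 811, 1250, 1420),
    ndep = c(12, 9, 7, 15, 11, 13, 18, 13.2, 21, 16),
    ph = c(5.1, 4.6, 4.9, 5.6, 5.2, 4.4, 5.9, 5.3, 4.8, 5.0),
    soc = c(42, 58, 36, 61, 48, 52, 39, 55, 66, 47),
    cn = c(14, 17, 13, 15, 16, 18, 12, 15, 19, 14),
    bd = c(0.8, 0.7, 0.9, 0.6, 0.75, 0.85, 0.95, 0.7, 0.65, 0.8),
    soil_temp = c(8, 9.5, 6.2, 11, 9.1, 10.4, 12.3, 9.0, 13.1, 10.8),
    delta_t = delta_t,
    wfps = c(38, 45, 33, 52, 41, 47, 55, 40, 58, 50),
    delta_wfps_pct = dw,
    n2o_control = n2o_control,
    n2o_warmed = n2o_control * (1 + rrn_val * delta_t)
  )
}

#' Headline warming-response report
#'
#' Assembles the treatment contrast of an experiment into one report: per
#' species the observed percent change of cumulative flux under warming, the
#' Q10-expected change, the shortfall of observed relative to expected, the
#' N2 estimate scaled from N2O and moisture, and the total (NO + N2O + N2)
#' response. The total change equals the control-flux-weighted combination
#' of the per-species changes by construction.
#'
#' @param experiment a `flux_experiment` from [simulate_experiment()], or
#'   any list with elements `daily_fluxes` (a `daily_flux` table with both
#'   treatments and species) and `soil_daily` (treatment-level daily `wfps`),
#'   plus `delta_t` (realized warming, degrees C).
#' @param q10 named vector of apparent Q10 per species used for the
#'   counterfactual (defaults: NO 3.5, N2O 2.1, N2 2.6).
#' @param n2_model an [n2_scaling_model()].
#' @param snow_policy passed to [cumulative_flux()] (NO annualization).
#' @return object of class `warming_summary`: data.frame `species_table`
#'   (species, control and warmed kg N ha-1 y-1, observed/expected/shortfall
#'   percent), `total` row, `delta_t`, `seasonal` (per-season shares).
#' @export
warming_summary <- function(experiment,
                            q10 = c(NO = 3.5, N2O = 2.1, N2 = 2.6),
                            n2_model = n2_scaling_model(),
                            snow_policy = "no_winter_zero") {
  daily <- experiment$daily_fluxes
  soil <- experiment$soil_daily
  delta_t <- experiment$delta_t
  if (is.null(daily) || is.null(delta_t))
    stop("experiment must carry daily_fluxes and delta_t")
  n_years <- length(unique(daily$year))
  ann <- cumulative_flux(daily, snow_policy = snow_policy, label = "annual")
  ann$kg_n_ha <- ann$kg_n_ha / n_years

  species_present <- unique(ann$species)
  rows <- list()
  for (sp in c("NO", "N2O")) {
    if (!sp %in% species_present) {
      message("species ", sp, " missing; partial report")
      next
    }
    xc <- ann$kg_n_ha[ann$species == sp & ann$treatment == "control"]
    xw <- ann$kg_n_ha[ann$species == sp & ann$treatment == "warmed"]
    evo <- expected_vs_observed(xc, xw, q10[[sp]], delta_t)
    rows[[sp]] <- data.frame(species = sp, control_kg = xc, warmed_kg = xw,
                             evo)
  }
  if (!is.null(soil) && "N2O" %in% species_present && "N2" %in% names(q10)) {
    n2 <- tryCatch(seasonal_n2(daily, soil, n2_model), error = function(e) NULL)
    if (!is.null(n2)) {
      xc <- n2$kg_n_ha[n2$treatment == "control"] / n_years
      xw <- n2$kg_n_ha[n2$treatment == "warmed"] / n_years
      if (length(xc) && length(xw) && xc != 0) {
        evo <- expected_vs_observed(xc, xw, q10[["N2"]], delta_t)
        rows[["N2"]] <- data.frame(species = "N2", control_kg = xc,
                                   warmed_kg = xw, evo)
      }
    }
  }
  if (!length(rows)) stop("no species with both treatments")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tot_c <- sum(tab$control_kg)
  tot_w <- sum(tab$warmed_kg)
  wts <- tab$control_kg / tot_c
  total <- data.frame(
    control_kg = tot_c, warmed_kg = tot_w,
    observed_change_pct = (tot_w / tot_c - 1) * 100,
    expected_increase_pct = sum(wts * tab$expected_increase_pct)
  )
  seasonal <- tryCatch(
    seasonal_partition(daily, snow_policy = snow_policy),
    error = function(e) NULL)
  structure(list(species_table = tab, total = total, delta_t = delta_t,
                 seasonal = seasonal, q10 = q10),
            class = "warming_summary")
}

#' @export
print.warming_summary <- function(x, ...) {
  cat(sprintf("<warming_summary> warming +%.1f C\n", x$delta_t))
  t <- x$species_table
  for (i in seq_len(nrow(t)))
    cat(sprintf(
      "  %-4s control %5.2f, warmed %5.2f kg N/ha/y | observed %+6.1f %%, Q10-expected %+5.1f %%, shortfall %+6.1f %%\n",
      t$species[i], t$control_kg[i], t$warmed_kg[i],
      t$observed_change_pct[i], t$expected_increase_pct[i],
      t$shortfall_pct[i]))
  cat(sprintf(
    "  total %5.2f -> %5.2f kg N/ha/y (observed %+.1f %%, expected %+.1f %%)\n",
    x$total$control_kg, x$total$warmed_kg, x$total$observed_change_pct,
    x$total$expected_increase_pct))
  invisible(x)
}
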