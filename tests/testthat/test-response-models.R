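exact_bins <- function(A, k, temps = seq(5, 25, by = 0.5)) {
  data.frame(bin_center = temps, bin_width = 0.5,
             mean_flux = A * exp(k * temps), n = 10L)
}

test_that("binning is left-closed right-open at the stated widths", {
  d <- data.frame(mean_flux = c(1, 2, 3), temp_mineral = c(10.1, 10.4, 10.6))
  b <- bin_fluxes(d, "temperature", width = 0.5)
  expect_equal(nrow(b), 2L)
  expect_equal(b$n, c(2L, 1L))
  expect_equal(b$mean_flux, c(1.5, 3))
  one <- bin_fluxes(data.frame(mean_flux = 4, temp_mineral = 12.3),
                    "temperature")
  expect_equal(nrow(one), 1L)
  uni <- bin_fluxes(data.frame(mean_flux = rep(7, 30),
                               wfps = runif(30, 20, 60)), "wfps")
  expect_true(all(uni$mean_flux == 7))
})

test_that("bin width and season filters are validated", {
  d <- data.frame(mean_flux = 1:5, temp_mineral = 1:5, doy = c(10, 150, 200, 250, 350))
  expect_error(bin_fluxes(d, "temperature", width = 0), "positive")
  b <- bin_fluxes(d, "temperature", season = c(121, 304))
  expect_equal(sum(b$n), 3L)
  expect_error(bin_fluxes(d[0, ], "temperature"), "no matched")
})

test_that("exponential fit round-trips noiseless bins to machine accuracy", {
  b <- exact_bins(2, log(3.5) / 10)
  fit <- fit_temperature_response(b)
  expect_lt(abs(fit$q10 - 3.5), 1e-6)
  expect_lt(abs(fit$A - 2), 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
  expect_equal(fit$q10, q10_from_k(fit$k))        # stored Q10 identity, exact
})

test_that("constant fluxes fit to k = 0, Q10 = 1", {
  b <- exact_bins(5, 0)
  fit <- fit_temperature_response(b)
  expect_lt(abs(fit$k), 1e-9)
  expect_equal(fit$q10, 1, tolerance = 1e-8)
})

test_that("temperature fit guards its preconditions", {
  expect_error(fit_temperature_response(exact_bins(2, 0.1)[1:4, ]), "5 bins")
  narrow <- exact_bins(2, 0.1, temps = seq(10, 12, by = 0.5))
  expect_error(fit_temperature_response(narrow), "span")
  neg <- exact_bins(2, 0.1)
  neg$mean_flux <- -neg$mean_flux
  expect_error(fit_temperature_response(neg), "positive mean fluxes")
})

test_that("q10_from_k evaluates the exponential identity", {
  expect_equal(q10_from_k(0), 1)
  expect_equal(q10_from_k(log(3.5) / 10), 3.5, tolerance = 1e-12)
  expect_equal(q10_from_k(0.12528), 3.5, tolerance = 1e-3)
  expect_equal(q10_from_k(log(2.1) / 10), 2.1, tolerance = 1e-12)
  expect_error(q10_from_k(NA), "finite")
})

test_that("fit scale equivariance: scaling fluxes scales A and leaves k", {
  b <- exact_bins(2, 0.08)
  b$mean_flux <- b$mean_flux * (1 + 0.03 * sin(seq_len(nrow(b))))
  f1 <- fit_temperature_response(b)
  b5 <- b
  b5$mean_flux <- 5 * b$mean_flux
  f5 <- fit_temperature_response(b5)
  expect_equal(f5$k, f1$k, tolerance = 1e-8)
  expect_equal(f5$A, 5 * f1$A, tolerance = 1e-6)
})

test_that("binned fit approaches the unbinned exponential as bins narrow", {
  set.seed(9)
  temps <- runif(4000, 5, 25)
  d <- data.frame(mean_flux = 2 * exp(0.1 * temps), temp_mineral = temps)
  err <- sapply(c(4, 1, 0.25), function(w) {
    f <- fit_temperature_response(bin_fluxes(d, "temperature", width = w))
    abs(f$k - 0.1)
  })
  expect_true(all(diff(err) < 1e-6))   # discretization error shrinks with width
  expect_lt(err[3], 1e-3)
})

test_that("quadratic moisture fit recovers an exact parabola and its vertex", {
  w <- seq(20, 50, by = 1)
  b <- data.frame(bin_center = w, bin_width = 1,
                  mean_flux = 10 - 0.02 * (w - 35)^2, n = 5L)
  fit <- fit_moisture_response(b)
  expect_equal(fit$optimum, 35, tolerance = 1e-9)
  expect_equal(fit$c2, -0.02, tolerance = 1e-9)
  expect_gt(fit$r2, 1 - 1e-12)
  # symmetric bins about the vertex recover it exactly through -c1/(2 c2)
  expect_equal(-fit$c1 / (2 * fit$c2), 35, tolerance = 1e-9)
})

test_that("moisture fit refuses inadmissible optima and degenerate designs", {
  w <- seq(20, 50, by = 2)
  lin <- data.frame(bin_center = w, bin_width = 2, mean_flux = 0.3 * w, n = 2L)
  fit <- fit_moisture_response(lin)
  expect_true(is.na(fit$optimum))
  expect_error(fit_moisture_response(lin[1:5, ]), "6 bins")
  same <- data.frame(bin_center = rep(30, 8), bin_width = 1,
                     mean_flux = rnorm(8), n = 1L)
  expect_error(fit_moisture_response(same), "degenerate")
})

test_that("Q10-expected counterfactual matches the power-law oracles", {
  expect_equal(q10_expected_flux(7, 3.5, 0), 7)
  expect_equal(q10_expected_flux(100, 3.5, 2), 100 * 3.5^0.2, tolerance = 1e-12)
  expect_equal(q10_expected_flux(100, 3.5, 2), 128.47, tolerance = 0.005)
  expect_equal(q10_expected_flux(100, 2.1, 2), 116.0, tolerance = 0.005)
  expect_error(q10_expected_flux(1, -2, 1), "positive")
})

test_that("counterfactual composition: two steps equal one combined step", {
  one <- q10_expected_flux(q10_expected_flux(50, 2.6, 1.2), 2.6, 0.8)
  expect_equal(one, q10_expected_flux(50, 2.6, 2.0), tolerance = 1e-12)
})

test_that("expected_vs_observed reproduces the printed shortfalls", {
  no <- expected_vs_observed(100, 81, 3.5, 2)
  expect_equal(no$expected_increase_pct, (3.5^0.2 - 1) * 100, tolerance = 1e-9)
  expect_equal(round(no$shortfall_pct), -37)
  n2o <- expected_vs_observed(100, 84, 2.1, 2)
  expect_equal(round(n2o$shortfall_pct), -28)
  same <- expected_vs_observed(10, q10_expected_flux(10, 3.5, 2), 3.5, 2)
  expect_equal(same$shortfall_pct, 0, tolerance = 1e-9)
  expect_error(expected_vs_observed(0, 1, 3.5, 2), "zero control")
})
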