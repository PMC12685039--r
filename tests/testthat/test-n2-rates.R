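test_that("N2 scaling model matches the linear-ratio oracles", {
  root <- 1.10 / 0.13                      # ~8.46 % WFPS
  expect_equal(suppressWarnings(estimate_n2(10, root))$n2_flux, 0, tolerance = 1e-12)
  expect_equal(estimate_n2(18, 35)$n2_flux, (0.13 * 35 - 1.10) * 18,
               tolerance = 1e-12)          # 62.1
  expect_equal(estimate_n2(0, 50)$n2_flux, 0)
  # below the root the ratio clamps to zero rather than going negative
  expect_equal(estimate_n2(10, 9)$ratio, max(0, 0.13 * 9 - 1.10))
  expect_gte(min(estimate_n2(c(5, 10), c(9.1, 60))$n2_flux), 0)
})

test_that("negative N2O days yield missing N2 with a flag", {
  est <- estimate_n2(c(-3, 12), c(40, 40))
  expect_true(is.na(est$n2_flux[1]))
  expect_equal(est$flag[1], "negative_n2o")
  expect_false(is.na(est$n2_flux[2]))
})

test_that("out-of-validity WFPS warns but still computes", {
  m <- n2_scaling_model(validity = c(20, 60))
  expect_warning(est <- estimate_n2(10, 70, m), "calibration range")
  expect_equal(est$n2_flux, (0.13 * 70 - 1.10) * 10)
  expect_error(estimate_n2(10, 120), "\\[0, 100\\]")
  expect_error(n2_scaling_model(slope = -0.1), "positive")
})

test_that("seasonal N2 is linear in the N2O series through a constant ratio", {
  d <- constant_daily(6, species = "N2O")
  soil <- data.frame(year = 1L, doy = 1:365, treatment = "control",
                     wfps = (3 + 1.10) / 0.13)        # ratio exactly 3
  n2 <- seasonal_n2(d, soil)
  base <- cumulative_flux(d, period = season_calendar()$growing,
                          snow_policy = "none")
  expect_equal(n2$kg_n_ha, 3 * base$kg_n_ha, tolerance = 1e-9)
  expect_equal(n2$species, "N2")
  zero <- seasonal_n2(constant_daily(0, species = "N2O"), soil)
  expect_equal(zero$kg_n_ha, 0)
})

test_that("net rates reproduce the incubation arithmetic", {
  rec <- data.frame(nh4_before = 10, no3_before = 5, nh4_after = 12,
                    no3_after = 9, days = 7)
  rt <- net_rates(rec)
  expect_equal(rt$r_miner, 6 / 7, tolerance = 1e-12)
  expect_equal(rt$r_nitr, 4 / 7, tolerance = 1e-12)
  same <- net_rates(data.frame(nh4_before = 3, no3_before = 2,
                               nh4_after = 3, no3_after = 2, days = 7))
  expect_equal(same$r_miner, 0)
  expect_equal(same$r_nitr, 0)
  neg <- net_rates(data.frame(nh4_before = 3, no3_before = 5,
                              nh4_after = 3, no3_after = 4, days = 7))
  expect_lt(neg$r_nitr, 0)                  # consumption is not clipped
  expect_error(net_rates(data.frame(nh4_before = 1, no3_before = 1,
                                    nh4_after = 1, no3_after = 1, days = 0)),
               "positive")
})

test_that("mineralization decomposes exactly into nitrification + ammonification", {
  set.seed(4)
  rec <- data.frame(nh4_before = runif(30, 1, 10), no3_before = runif(30, 1, 10),
                    nh4_after = runif(30, 1, 12), no3_after = runif(30, 1, 12),
                    days = 7)
  rt <- net_rates(rec)
  ammonif <- (rec$nh4_after - rec$nh4_before) / rec$days
  expect_equal(rt$r_miner, rt$r_nitr + ammonif, tolerance = 1e-12)
})

test_that("Arrhenius fit round-trips and predicts with the right Q10", {
  temps <- c(5, 10, 15, 20, 25)
  b <- log(2) / 10
  rates <- 0.4 * exp(b * temps)
  fit <- fit_arrhenius(temps, rates)
  expect_lt(abs(fit$b - b), 1e-6)
  expect_lt(abs(fit$a - 0.4), 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(predict_rate(fit, 25) / predict_rate(fit, 15), 2,
               tolerance = 1e-6)
  expect_equal(predict_rate(fit, 15), 0.4 * exp(b * 15), tolerance = 1e-6)
  expect_warning(predict_rate(fit, 40), "extrapolating")
})

test_that("constant rates fit to b = 0 and degenerate gradients error", {
  fit <- fit_arrhenius(c(5, 10, 15, 20, 25), rep(0.7, 5))
  expect_equal(fit$b, 0)
  expect_error(fit_arrhenius(c(10, 10, 10), c(1, 2, 3)), "distinct")
})

test_that("a cooler-but-wetter contrast can offset the temperature term", {
  # control at 15 C vs warmed at 17 C with the warmed baseline reduced 25 %
  b <- log(2) / 10
  fit_c <- fit_arrhenius(c(5, 10, 15, 20, 25), 1.0 * exp(b * c(5, 10, 15, 20, 25)))
  fit_w <- fit_arrhenius(c(5, 10, 15, 20, 25), 0.75 * exp(b * c(5, 10, 15, 20, 25)))
  ratio <- predict_rate(fit_w, 17) / predict_rate(fit_c, 15)
  expect_equal(ratio, 0.75 * exp(2 * b), tolerance = 1e-6)
})

test_that("Arrhenius and flux-exponential fits agree on identical data", {
  temps <- seq(5, 25, by = 2.5)
  y <- 1.3 * exp(0.09 * temps) * (1 + 0.02 * cos(temps))
  arr <- fit_arrhenius(temps, y)
  bins <- data.frame(bin_center = temps, bin_width = 2.5, mean_flux = y,
                     n = 1L)
  tr <- fit_temperature_response(bins)
  expect_lt(abs(arr$b - tr$k), 1e-9)
  expect_lt(abs(arr$a - tr$A), 1e-9)
})
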