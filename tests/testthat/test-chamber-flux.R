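test_that("a chamber that never departs from ambient has exactly zero flux", {
  cl <- simulate_closure(0, "NO", ambient_ppb = 1, noise_sd = 0)
  rec <- compute_flux(cl)
  expect_identical(rec$flux, 0)
  expect_identical(rec$accumulation_term, 0)
  expect_identical(rec$dynamic_term, 0)
})

test_that("accumulation term reproduces the dimensional-analysis oracle", {
  # 60 nmol/mol/h slope, dilution zeroed, STP: 1 nmol/mol NO = 0.625 ug N m-3,
  # so flux = 60 * 0.625 * V/A = 60 * 0.625 * 0.091/0.18
  cl <- linear_closure(60, "NO", T_K = 273, P_hPa = 1013)
  rec <- compute_flux(cl)
  oracle <- 60 * 0.625 * 0.091 / 0.18
  expect_equal(rec$accumulation_term, oracle, tolerance = 1e-9)
  expect_equal(rec$dynamic_term, 0, tolerance = 1e-9)
  expect_equal(rec$flux, oracle, tolerance = 1e-9)
  expect_equal(rec$slope, 60, tolerance = 1e-9)
})

test_that("flux record invariants hold: flux = accumulation + dynamic", {
  for (F in c(0.5, 20)) {
    rec <- compute_flux(simulate_closure(F, "N2O", ambient_ppb = 330,
                                         noise_sd = 0.3))
    expect_equal(rec$flux, rec$accumulation_term + rec$dynamic_term,
                 tolerance = 1e-9)
    expect_true(is.finite(rec$slope_r2))
  }
})

test_that("estimator recovers known fluxes within 10 % for both species", {
  for (sp in c("NO", "N2O")) {
    amb <- if (sp == "NO") 1 else 330
    for (F in c(1, 10, 100)) {
      rec <- compute_flux(simulate_closure(F, sp, ambient_ppb = amb,
                                           noise_sd = 0))
      expect_lt(abs(rec$flux / F - 1), 0.10)
    }
  }
})

test_that("estimator error on noiseless closures matches the closed-form bias", {
  # independent oracle: OLS slope and window mean of the exact solution
  g <- chamber_geometry()
  for (sp in c("NO", "N2O")) {
    F <- 10
    amb <- if (sp == "NO") 1 else 330
    win <- warmflux:::regression_window(sp)
    t_s <- seq(win[1], win[2], by = g$dt_s)
    tau <- g$V / g$Q * 3600
    shape <- 1 - exp(-(t_s - g$flush_min * 60) / tau)
    th <- t_s / 3600
    slope_shape <- sum((th - mean(th)) * shape) / sum((th - mean(th))^2)
    # excess concentration is F*A/Q*shape, so the two Eq.-style terms give
    # flux = F * (slope(shape)*V/Q + mean(shape))
    predicted <- F * (slope_shape * g$V / g$Q + mean(shape))
    rec <- compute_flux(simulate_closure(F, sp, ambient_ppb = amb,
                                         noise_sd = 0, T_C = 15))
    expect_equal(rec$flux, predicted, tolerance = 5e-4)  # 3 significant figures
  }
})

test_that("flux estimation is linear in the concentration excursion", {
  cl <- simulate_closure(10, "NO", ambient_ppb = 1, noise_sd = 0)
  rec1 <- compute_flux(cl)
  cl3 <- cl
  cl3$samples$conc <- 1 + 3 * (cl$samples$conc - 1)
  cl3$ambient_C <- 1
  rec3 <- compute_flux(cl3)
  expect_equal(rec3$flux, 3 * rec1$flux, tolerance = 1e-9)
})

test_that("identical series as NO vs N2O differ by the nitrogen mass ratio", {
  # samples restricted to the common window so both species regress on the
  # same points; M_N ratio N2O:NO = 28:14 = 2
  g <- chamber_geometry()
  t_s <- c(seq(300, 600, by = g$dt_s), 1210, 1220, 1230)
  conc <- c(5 + (seq(300, 600, by = g$dt_s)) * 0.01, 5, 5, 5)
  phase <- c(rep("closure", length(t_s) - 3), rep("ambient", 3))
  base <- list(samples = data.frame(t_s = t_s, conc = conc, phase = phase),
               T_K = 293, P_hPa = 1000, ambient_C = 5, geometry = g,
               chamber_id = "x", plot_id = "p", treatment = "control",
               true_flux = NA_real_)
  no <- structure(c(base, species = "NO"), class = "closure_series")
  n2o <- structure(c(base, species = "N2O"), class = "closure_series")
  expect_equal(compute_flux(n2o)$flux, 2 * compute_flux(no)$flux,
               tolerance = 1e-12)
})

test_that("too few window samples yields a flagged record without a flux", {
  g <- chamber_geometry()
  cl <- simulate_closure(10, "NO", noise_sd = 0)
  keep <- cl$samples$t_s < 320 | cl$samples$t_s > 1200
  cl$samples <- cl$samples[keep, ]
  rec <- compute_flux(cl)
  expect_true(is.na(rec$flux))
  expect_match(rec$qc_flags, "too_few_samples")
})

test_that("non-finite concentrations and disordered samples are errors", {
  cl <- simulate_closure(10, "NO", noise_sd = 0)
  bad <- cl
  bad$samples$conc[5] <- NaN
  expect_error(compute_flux(bad), "non-finite")
  swap <- cl
  swap$samples <- swap$samples[rev(seq_len(nrow(swap$samples))), ]
  expect_error(compute_flux(swap), "time-ordered")
})

test_that("spike filter removes isolated excursions and records the fact", {
  cl <- simulate_closure(10, "NO", ambient_ppb = 1, noise_sd = 0.05)
  i <- which(cl$samples$phase == "closure" & cl$samples$t_s > 350)[3]
  clean <- compute_flux(cl)
  cl$samples$conc[i] <- cl$samples$conc[i] + 50
  rec <- compute_flux(cl)
  expect_match(rec$qc_flags, "spikes_removed:1")
  expect_lt(abs(rec$flux - clean$flux), 0.5)
})

test_that("mass-concentration input dialect skips the ppb conversion", {
  cl <- linear_closure(60, "NO", T_K = 273, P_hPa = 1013)
  rec <- compute_flux(cl, units = "ug_m3")
  expect_equal(rec$flux, 60 * 0.091 / 0.18, tolerance = 1e-9)
})
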