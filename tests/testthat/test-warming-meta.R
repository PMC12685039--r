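test_that("lnRR matches closed forms and guards non-positive inputs", {
  expect_equal(lnrr(2, 2), 0)
  expect_equal(lnrr(2, 1), log(2), tolerance = 1e-12)
  expect_true(is.na(suppressWarnings(lnrr(-1, 2))))
  expect_true(is.na(lnrr(0, 2)))
  set.seed(2)
  a <- runif(30, 0.1, 5); b <- runif(30, 0.1, 5)
  expect_equal(lnrr(a, b), -lnrr(b, a), tolerance = 1e-12)
})

test_that("lnRR and the relative effect agree to first order for small effects", {
  x_c <- 1
  for (eps in c(0.001, 0.01, 0.05)) {
    rel <- eps
    lr <- lnrr(x_c * (1 + eps), x_c)
    expect_lt(abs(lr - rel), rel^2 / 2 * 1.01 + 1e-12)
  }
})

test_that("RRn standardizes per degree and scales with delta_T", {
  expect_equal(rrn(1.2, 1.0, 2), 0.1, tolerance = 1e-12)
  expect_equal(rrn(3, 3, 5), 0)
  expect_equal(rrn(1.2, 1.0, 4), rrn(1.2, 1.0, 2) / 2, tolerance = 1e-12)
  expect_error(rrn(1, 1, 0), "positive")
  expect_error(rrn(1, 0, 2), "non-zero")
})

test_that("effect table summarizes paired samples with a seeded bootstrap", {
  pairs <- data.frame(variable = rep(c("nh4", "mbn"), each = 4),
                      control = c(10, 11, 9, 10, 5, 6, 5, 5),
                      warmed = c(9, 10, 8.5, 9.5, 5, 6, 5, 5))
  et <- effect_table(pairs, seed = 3)
  expect_equal(et$relative_effect_pct[et$variable == "mbn"], 0)
  expect_lt(et$relative_effect_pct[et$variable == "nh4"], 0)
  expect_false(is.na(et$se_pct[1]))
  et2 <- effect_table(pairs, seed = 3)
  expect_identical(et, et2)                          # bootstrap is seeded
  one <- effect_table(data.frame(variable = "x", control = 2, warmed = 3))
  expect_true(is.na(one$se_pct))
  expect_equal(one$relative_effect_pct, 50)
  alleq <- data.frame(variable = "y", control = c(1, 2), warmed = c(1, 2))
  expect_equal(effect_table(alleq)$relative_effect_pct, 0)
})

test_that("O-horizon moisture warming effect is negative across seeds", {
  hits <- vapply(1:5, function(s) {
    cl <- simulate_climate(tiny_config(seed = s))
    gs <- cl[doy_in_growing_season(cl$doy), ]
    m <- tapply(gs$grav_o, gs$treatment, mean)
    unname(m["warmed"] < m["control"])
  }, logical(1))
  expect_true(all(hits))
})

test_that("meta regression recovers an exact linear relation", {
  st <- data.frame(site_id = letters[1:6], delta_t = rep(2, 6),
                   delta_wfps_pct = c(-10, -6, -2, 0, 3, 6))
  st$rrn <- 0.05 + 0.01 * st$delta_wfps_pct
  st$n2o_control <- 1
  st$n2o_warmed <- 1 * (1 + st$rrn * st$delta_t)
  st$rrn <- NULL                                      # force recomputation
  mr <- meta_regression(st)
  expect_equal(mr$slope, 0.01, tolerance = 1e-9)
  expect_equal(mr$intercept, 0.05, tolerance = 1e-9)
  expect_equal(mr$r2, 1, tolerance = 1e-9)
})

test_that("meta regression guards degenerate designs and sample size", {
  st <- synthetic_site_table()
  st$delta_wfps_pct <- 5
  expect_error(meta_regression(st), "degenerate")
  expect_error(meta_regression(synthetic_site_table()[1:3, ]), "at least 4")
  expect_error(meta_regression(synthetic_site_table(), predictor = "nope"),
               "not found")
})

test_that("meta regression is invariant to row order and affine predictor scaling", {
  st <- synthetic_site_table()
  mr <- meta_regression(st)
  sh <- meta_regression(st[sample.int(nrow(st)), ])
  expect_equal(sh$slope, mr$slope, tolerance = 1e-12)
  expect_equal(sh$r2, mr$r2, tolerance = 1e-12)
  st2 <- st
  st2$delta_wfps_pct <- st2$delta_wfps_pct / 100 + 0.3   # fractional units
  mr2 <- meta_regression(st2)
  expect_equal(mr2$r2, mr$r2, tolerance = 1e-12)
  expect_equal(mr2$slope, mr$slope * 100, tolerance = 1e-9)
})

test_that("seeded permutation of the response destroys the relation", {
  st <- synthetic_site_table()
  st$rrn <- rrn(st$n2o_warmed, st$n2o_control, st$delta_t)
  set.seed(8)
  r2s <- vapply(1:200, function(i) {
    st$rrn <- sample(st$rrn)
    meta_regression(st)$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
})

test_that("the bundled synthetic site table encodes its calibrated pattern", {
  st <- synthetic_site_table()
  mr <- meta_regression(st)
  expect_equal(mr$r2, 0.45, tolerance = 1e-9)
  expect_gt(mr$slope, 0)                    # drier sites respond more negatively
  # moisture losses concentrate below ~1000 mm annual precipitation
  expect_true(all(st$map_mm[st$delta_wfps_pct < -5] < 1000))
  csv <- read.csv(system.file("extdata", "site_table_synthetic.csv",
                              package = "warmflux"))
  expect_equal(csv$n2o_warmed, st$n2o_warmed, tolerance = 1e-8)
  expect_equal(meta_regression(csv)$r2, 0.45, tolerance = 1e-6)
})

test_that("warming summary on identical treatments shows pure Q10 shortfall", {
  e <- simulate_experiment(tiny_config(seed = 3, warming_delta_T = 0),
                           measurement = "daily")
  e$delta_t <- 2   # evaluate the counterfactual at a nominal +2 C
  ws <- suppressWarnings(warming_summary(e))
  t <- ws$species_table
  expect_lt(max(abs(t$observed_change_pct)), 1e-9)
  for (i in seq_len(nrow(t))) {
    fac <- 1 + t$expected_increase_pct[i] / 100
    expect_equal(t$shortfall_pct[i], (1 / fac - 1) * 100, tolerance = 1e-9)
  }
})

test_that("total N change equals the flux-weighted combination of species changes", {
  e <- simulate_experiment(tiny_config(seed = 5), measurement = "daily")
  ws <- suppressWarnings(warming_summary(e))
  t <- ws$species_table
  w <- t$control_kg / sum(t$control_kg)
  expect_equal(ws$total$observed_change_pct,
               sum(w * t$observed_change_pct), tolerance = 1e-9)
  expect_equal(ws$total$expected_increase_pct,
               sum(w * t$expected_increase_pct), tolerance = 1e-9)
})
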