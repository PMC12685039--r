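make_records <- function(flux, chamber_id = "c1", treatment = "control",
                         species = "NO", year = 1L, doy = 150L) {
  data.frame(chamber_id = chamber_id, plot_id = "p1", treatment = treatment,
             species = species, year = year, doy = doy, flux = flux,
             qc_flags = "")
}

test_that("a single flux gives its own daily mean and no SE", {
  d <- daily_aggregate(make_records(5))
  expect_equal(d$mean_flux, 5)
  expect_true(is.na(d$se))
  expect_equal(d$n_chambers, 1L)
})

test_that("both treatments produce one daily row each", {
  rec <- rbind(make_records(5, "c1", "control"),
               make_records(7, "c2", "warmed"))
  d <- daily_aggregate(rec)
  expect_equal(nrow(d), 2L)
  expect_setequal(d$treatment, c("control", "warmed"))
})

test_that("chambers are weighted equally regardless of closure counts", {
  rec <- rbind(make_records(c(2, 2, 2), "c1"),  # 3 closures
               make_records(8, "c2"))           # 1 closure
  d <- daily_aggregate(rec)
  expect_equal(d$mean_flux, 5)                  # (2+8)/2, not (2+2+2+8)/4
  expect_equal(d$n_fluxes, 4L)
})

test_that("flagged records are excluded and counted", {
  rec <- make_records(c(5, 500), "c1")
  rec$qc_flags[2] <- "spikes_removed:3"
  d <- daily_aggregate(rec)
  expect_equal(d$mean_flux, 5)
  expect_equal(d$n_excluded, 1L)
})

test_that("a simulated constant-flux day is recovered within its noise CI", {
  cfg <- sim_config()
  est <- warmflux:::simulate_and_estimate_closures(
    rep(10, 60), "NO", rep(15, 60), cfg, seed = 3)
  rec <- make_records(est$flux,
                      chamber_id = rep(sprintf("c%d", 1:15), each = 4))
  d <- daily_aggregate(rec)
  expect_lt(abs(d$mean_flux - 10), 4 * d$se + 0.5)
})

test_that("constant flux integrates to the arithmetic oracle", {
  d <- constant_daily(10)  # N2O: no snow masking by default policy
  cf <- cumulative_flux(d)
  expect_equal(cf$kg_n_ha, 10 * 24 * 365 * 1e-5, tolerance = 1e-12)  # 0.876
  expect_equal(cf$coverage, 1)
})

test_that("the snow policy zeroes NO between Dec 1 and Mar 31", {
  d <- constant_daily(10, species = "NO")
  masked <- cumulative_flux(d)
  open <- cumulative_flux(d, snow_policy = "none")
  expect_equal(open$kg_n_ha, 0.876, tolerance = 1e-12)
  expect_equal(masked$kg_n_ha, 0.876 * (365 - 121) / 365, tolerance = 1e-12)
})

test_that("an interior missing day is interpolated exactly for constant data", {
  d <- constant_daily(10)
  full <- cumulative_flux(d)
  gap <- cumulative_flux(d[d$doy != 180, ])
  expect_equal(gap$kg_n_ha, full$kg_n_ha, tolerance = 1e-12)
  expect_lt(gap$coverage, 1)
})

test_that("gaps beyond the cap flag the period value", {
  d <- constant_daily(10)
  d <- d[d$doy < 100 | d$doy > 140, ]
  cf <- cumulative_flux(d)
  expect_equal(cf$flag, "gap_exceeds_cap")
})

test_that("integration is additive over adjacent periods", {
  set.seed(42)
  d <- constant_daily(0)
  d$mean_flux <- rlnorm(nrow(d), 1, 0.5)
  a <- cumulative_flux(d, period = c(1L, 100L))$kg_n_ha
  b <- cumulative_flux(d, period = c(101L, 200L))$kg_n_ha
  ab <- cumulative_flux(d, period = c(1L, 200L))$kg_n_ha
  expect_equal(a + b, ab, tolerance = 1e-12)
})

test_that("empty periods error and empty aggregates message", {
  d <- constant_daily(10)
  expect_error(cumulative_flux(d[0, ]), "empty period")
  expect_error(cumulative_flux(d, period = c(200L, 100L)), "precedes")
  rec <- make_records(NA_real_)
  expect_message(daily_aggregate(rec), "no QC-passing")
})

test_that("uniform flux partitions by season length and shares sum to one", {
  d <- constant_daily(10)
  sp <- seasonal_partition(d, snow_policy = "none")
  lens <- c(growing = 184, dormant_fall = 61, dormant_spring = 120)
  expect_equal(sp$share[match(names(lens), sp$season)],
               unname(lens / 365), tolerance = 1e-12)
  expect_equal(sum(sp$share), 1, tolerance = 1e-12)
})

test_that("a one-season calendar reduces to cumulative_flux", {
  d <- constant_daily(3)
  one <- seasonal_partition(d, calendar = list(all = c(1L, 365L)),
                            snow_policy = "none")
  expect_equal(one$kg_n_ha, cumulative_flux(d, snow_policy = "none")$kg_n_ha)
  expect_error(seasonal_partition(d, calendar = list(a = c(1L, 100L),
                                                     b = c(100L, 200L))),
               "overlap")
})

test_that("default synthetic NO puts 70-95 % of the annual flux in the growing season", {
  for (s in 1:2) {
    e <- simulate_experiment(sim_config(seed = s), measurement = "daily",
                             species = "NO", treatments = "control")
    sp <- seasonal_partition(e$daily_fluxes)
    share <- sp$share[sp$season == "growing"]
    expect_gt(share, 0.70)
    expect_lt(share, 0.95)
  }
})
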