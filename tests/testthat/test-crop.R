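# Heat units, canopy, stress, biomass and yield rules.

test_that("daily GDD follows the capped-and-clamped form", {
  # hand arithmetic: (28 + 12)/2 - 8 = 12
  expect_equal(daily_gdd(28, 12, 8, 30), 12)
  # base-temperature identity
  expect_equal(daily_gdd(8, 8, 8, 30), 0)
  # cap rule: tmax 40 capped at 30 -> (30 + 20)/2 - 8 = 17
  expect_equal(daily_gdd(40, 20, 8, 30), 17)
  # frost days clamp to zero, never negative
  expect_equal(daily_gdd(2, -6, 8, 30), 0)
  expect_error(daily_gdd(10, 12, 8, 30), "tmin")
})

test_that("early canopy growth matches the exponential closed form", {
  cc0 <- 0.05; ccx <- 0.95; cgc <- 0.007
  for (t in c(0, 50, 150, 250)) {
    expected <- cc0 * exp(cgc * t)
    if (expected <= ccx / 2) {
      expect_equal(canopy_cover_at(t, 0, cc0, ccx, cgc, 0.005), expected,
                   tolerance = 1e-12)
    }
  }
  # at emergence the cover is exactly CC0
  expect_equal(canopy_cover_at(0, 0, cc0, ccx, cgc, 0.005), cc0)
})

test_that("canopy cover never exceeds its maximum and declines in senescence", {
  cc0 <- 0.05; ccx <- 0.95; cgc <- 0.007; cdc <- 0.005
  tt <- seq(0, 3000, by = 25)
  cc <- vapply(tt, canopy_cover_at, numeric(1), t_senescence = 0,
               cc0 = cc0, ccx = ccx, cgc = cgc, cdc = cdc)
  expect_true(all(cc <= ccx + 1e-12))
  expect_true(all(diff(cc) >= -1e-12))  # monotone growth phase
  cc_sen <- vapply(seq(0, 800, by = 50), function(ts) {
    canopy_cover_at(2000, ts, cc0, ccx, cgc, cdc)
  }, numeric(1))
  expect_true(all(diff(cc_sen) < 0))
})

test_that("water stress coefficients interpolate linearly past the threshold", {
  taw <- 120
  expect_equal(water_stress_coefficients(0, taw, 0.5)$stomatal, 1)
  expect_equal(water_stress_coefficients(taw, taw, 0.5)$stomatal, 0)
  # p_up 0.5, Dr = 0.75 TAW -> halfway between threshold and TAW
  expect_equal(water_stress_coefficients(0.75 * taw, taw, 0.5)$stomatal, 0.5)
  # expansion stress engages at lower depletion than stomatal stress
  ks <- water_stress_coefficients(0.45 * taw, taw, 0.5)
  expect_lt(ks$expansion, 1)
  expect_equal(ks$stomatal, 1)
  expect_error(water_stress_coefficients(10, 0, 0.5), "TAW")
})

test_that("biomass accumulation is the normalized-transpiration sum", {
  expect_equal(biomass_increment(0, 4, 0.32), 0)
  # reference CO2 gives exactly f = 1
  expect_equal(f_co2(369.41), 1)
  # season sum identity
  set.seed(7)
  tr <- runif(40, 0, 5); et0 <- runif(40, 2, 6)
  total <- sum(biomass_increment(tr, et0, 0.15, co2 = 410, co2_sens = 0.2))
  expect_equal(total, 0.15 * f_co2(410, 0.2) * sum(tr / et0),
               tolerance = 1e-12)
  # C3 response: about +10% at +200 ppm; C4 about +2%
  expect_equal(f_co2(369.41 + 200, 0.2), 1.10, tolerance = 1e-9)
  expect_equal(f_co2(369.41 + 200, 0.04), 1.02, tolerance = 1e-9)
})

test_that("stress-adjusted yield follows the stated combination rule", {
  # unstressed identity: B 10, HI0 0.5 -> 5
  expect_equal(yield_at_harvest(10, 0.5), 5)
  # one of five flowering days failed: heat factor 1 - 1/5
  expect_equal(yield_at_harvest(10, 0.5, heat_fail_days = 1,
                                flowering_days = 5), 5 * 0.8)
  # all flowering days failed: floor at 0.05
  expect_equal(yield_at_harvest(10, 0.5, heat_fail_days = 5,
                                flowering_days = 5), 5 * 0.05)
  # removing stress never decreases yield
  y_stressed <- yield_at_harvest(10, 0.5, 2, 5, mean_ks_yield = 0.6)
  expect_gt(yield_at_harvest(10, 0.5), y_stressed)
})

test_that("heat-unit calibration closes on the reference calendar", {
  cfg <- tiny_config()
  w <- generate_weather(cfg, 1, noise = FALSE, years = 3)
  cal <- calibrate_heat_units(w, 120, 270, tbase = 8, tupp = 30)
  # oracle: direct mean of daily GDD sums over the window
  g <- daily_gdd(w$tmax, w$tmin, 8, 30)
  manual <- mean(vapply(unique(w$year), function(y) {
    sum(g[w$year == y & w$doy >= 120 & w$doy <= 270])
  }, numeric(1)))
  expect_equal(cal$gdd_maturity, manual, tolerance = 1e-9)
  # stage fractions partition the maturity requirement
  expect_equal(unname(cal$stages[["maturity"]]), cal$gdd_maturity)
  expect_equal(unname(cal$stages), unname(c(0.05, 0.40, 0.80, 1) * cal$gdd_maturity))
})

test_that("cross-year (winter crop) calibration uses the wrapped window", {
  cfg <- tiny_config()
  w <- generate_weather(cfg, 1, noise = FALSE, years = 3)
  cal <- calibrate_heat_units(w, 280, 190, tbase = 0, tupp = 26)
  expect_gt(cal$gdd_maturity, 0)
  g <- daily_gdd(w$tmax, w$tmin, 0, 26)
  y <- unique(w$year)[1]
  manual1 <- sum(g[(w$year == y & w$doy >= 280) |
                   (w$year == y + 1 & w$doy <= 190)])
  # deterministic mean climate: every wrapped season accumulates the same
  expect_equal(cal$gdd_maturity, manual1, tolerance = 1e-6)
})

test_that("a too-cold cell is flagged non-viable", {
  w <- tibble::tibble(year = rep(2001, 365), doy = 1:365,
                      tmax = rep(-2, 365), tmin = rep(-8, 365))
  expect_null(calibrate_heat_units(w, 100, 250, tbase = 8, tupp = 30))
})

test_that("calendar adjustment delays emergence and caps the season", {
  gdd <- rep(10, 200)
  moist <- rep(TRUE, 200)
  out <- adjust_calendar(gdd, moist, gdd_maturity = 1000,
                         reference_length = 110)
  expect_equal(out$emergence_offset, 1)
  expect_equal(out$harvest_offset, 100)  # 1000/10 days
  expect_true(out$matured)

  # dry seedbed for 10 days shifts emergence (and harvest) by 10 days
  moist10 <- c(rep(FALSE, 10), rep(TRUE, 190))
  out10 <- adjust_calendar(gdd, moist10, 1000, 110)
  expect_equal(out10$emergence_offset, 11)
  expect_equal(out10$harvest_offset, 110)

  # cold year: maturity unreachable within 1.15 L, season terminates at cap
  cold <- adjust_calendar(rep(4, 200), moist, 1000, 110)
  expect_false(cold$matured)
  expect_equal(cold$harvest_offset, ceiling(1.15 * 110))

  # warm year matures strictly earlier than the reference
  warm <- adjust_calendar(rep(12, 200), moist, 1000, 110)
  expect_lt(warm$harvest_offset, 100)
})
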