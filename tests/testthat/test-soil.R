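# Soil water balance primitives: runoff, mixing, drainage, capillary rise,
# extraction, and the daily step's colour conservation.

hyd <- soil_hydraulics("loam")
thick <- soil_profile("deep")

test_that("curve-number runoff matches the hand-evaluated closed form", {
  # CN 75, P 40 mm: S = 254(100/75 - 1) = 84.6667, 0.2S = 16.9333,
  # runoff = (40 - 16.9333)^2 / (40 + 0.8 * 84.6667), evaluated by hand.
  expect_equal(curve_number_runoff(40, 75), 4.9387788779, tolerance = 1e-9)
  expect_identical(curve_number_runoff(0, 75), 0)
  # P <= 0.2 S gives exactly zero
  expect_identical(curve_number_runoff(16.9, 75), 0)
  s <- 254 * (100 / 65 - 1)
  expect_identical(curve_number_runoff(0.2 * s, 65), 0)
  expect_error(curve_number_runoff(10, 0), "curve number")
})

test_that("bunds suppress runoff until ponding exceeds the bund height", {
  expect_identical(curve_number_runoff(50, 80, bund_height = 300, ponding = 100), 0)
  expect_equal(curve_number_runoff(50, 80, bund_height = 300, ponding = 280), 30)
})

test_that("runoff is always less than precipitation", {
  for (p in c(1, 10, 50, 120, 300)) {
    for (cn in c(60, 75, 90)) {
      expect_lt(curve_number_runoff(p, cn), p)
    }
  }
})

test_that("inflow mixing updates colour fractions by mass", {
  st <- soil_state(thick, hyd, initial = 0.15, colour = "green")
  st$M[, 2] <- 0  # empty compartment
  st <- mix_inflow(st, 2, 10, "green")
  tab <- soil_state_table(st)
  expect_equal(tab$f_green[2], 1)
  expect_equal(tab$f_blue_i[2], 0)

  # 50 mm green + 50 mm blue_i -> 50/50 by mass
  st2 <- soil_state(thick, hyd, initial = "dry")
  st2$M[, 3] <- 0
  st2 <- mix_inflow(st2, 3, 50, "green")
  st2 <- mix_inflow(st2, 3, 50, "blue_i")
  tab2 <- soil_state_table(st2)
  expect_equal(tab2$f_green[3], 0.5)
  expect_equal(tab2$f_blue_i[3], 0.5)

  # zero inflow leaves the state unchanged
  st3 <- mix_inflow(st2, 3, 0, "blue_cr")
  expect_identical(st3$M, st2$M)
})

test_that("overfill beyond saturation is signalled, not clipped", {
  st <- soil_state(thick, hyd, initial = "fc")
  room <- st$sat_mm[1] - sum(st$M[, 1])
  expect_error(mix_inflow(st, 1, room + 5, "green"), class = "wf_overfill")
})

test_that("drainage cascades excess above field capacity at rate tau", {
  st <- soil_state(thick, hyd, initial = "fc")
  out <- drain(st)
  expect_equal(sum(out$percolation), 0)
  expect_equal(out$state$M, st$M)

  # one compartment 10 mm above FC with tau drains tau * 10 this day
  st2 <- soil_state(thick, hyd, initial = "fc")
  st2$M["green", 4] <- st2$M["green", 4] + 10
  before <- soil_water_total(st2)
  out2 <- drain(st2)
  moved <- sum(st2$M[, 4]) - sum(out2$state$M[, 4])
  expect_equal(moved, hyd$tau * 10, tolerance = 1e-12)
  # conservation: nothing left the profile (receiver below had room)
  expect_equal(soil_water_total(out2$state) + sum(out2$percolation), before,
               tolerance = 1e-9)
})

test_that("drainage conserves every colour", {
  st <- soil_state(thick, hyd, initial = "fc", colour = "green")
  st$M["blue_i", ] <- 15   # blue layered on top of FC: excess everywhere
  before <- wfcrop:::soil_colour_totals(st)
  out <- drain(st)
  after <- wfcrop:::soil_colour_totals(out$state) + out$percolation
  expect_equal(unname(after), unname(before), tolerance = 1e-9)
  expect_true(all(colSums(out$state$M) <= out$state$sat_mm + 1e-9))
})

test_that("capillary rise obeys the system, depth and drainage rules", {
  dry <- soil_state(thick, hyd, initial = "dry")
  # irrigated non-rice never receives capillary rise
  expect_equal(capillary_rise(dry, 1, "irrigated", FALSE)$flux, 0)
  # irrigated rice does
  expect_gt(capillary_rise(dry, 1, "irrigated", TRUE)$flux, 0)
  # deeper than 4 m: nothing
  expect_equal(capillary_rise(dry, 5, "rainfed")$flux, 0)
  # water table at the surface behaves as if drained to 1 m
  f0 <- capillary_rise(dry, 0, "rainfed")$flux
  f1 <- capillary_rise(dry, 1, "rainfed")$flux
  expect_equal(f0, f1)
  # flux decreases with depth
  f2 <- capillary_rise(dry, 2.5, "rainfed")$flux
  expect_lt(f2, f1)
  # wet lowest compartments gate the flux to zero
  fc <- soil_state(thick, hyd, initial = "fc")
  expect_equal(capillary_rise(fc, 1, "rainfed")$flux, 0)
  expect_error(capillary_rise(dry, -1, "rainfed"), "depth")
})

test_that("extraction carries donor colour fractions and respects limits", {
  # all-green profile: extracted ET has zero blue share
  st <- soil_state(thick, hyd, initial = "fc", colour = "green")
  rz <- root_zone_status(st, 1.0)
  out <- extract_evapotranspiration(st, 3, 4, rz$weights)
  expect_equal(out$evaporation[["blue_i"]] + out$evaporation[["blue_cr"]], 0)
  expect_equal(out$transpiration[["blue_i"]] + out$transpiration[["blue_cr"]], 0)
  expect_equal(sum(out$transpiration), 4, tolerance = 1e-9)

  # top compartment at wilting point: evaporation supply-limited to zero
  st2 <- soil_state(thick, hyd, initial = "fc")
  st2$M[, 1] <- 0
  st2$M["green", 1] <- st2$wp_mm[1]
  out2 <- extract_evapotranspiration(st2, 5, 0, rz$weights)
  expect_equal(sum(out2$evaporation), 0)
  expect_equal(out2$evap_deficit, 5)

  # uniform blue_i fraction 0.3 in the root zone: 10 mm transpired
  # carries exactly 3 mm blue_i
  st3 <- soil_state(thick, hyd, initial = "fc", colour = "green")
  w <- colSums(st3$M)
  st3$M["green", ] <- 0.7 * w
  st3$M["blue_i", ] <- 0.3 * w
  st3$M["blue_cr", ] <- 0
  out3 <- extract_evapotranspiration(st3, 0, 10, rz$weights)
  expect_equal(out3$transpiration[["blue_i"]], 3, tolerance = 1e-9)
})

test_that("the daily step conserves mass per colour on random days", {
  set.seed(401)
  st <- soil_state(thick, hyd, initial = 0.2, colour = "green")
  for (i in 1:60) {
    before <- wfcrop:::soil_colour_totals(st)
    out <- step_water_balance(
      st, precip = rgamma(1, 0.6, scale = 12), et0 = runif(1, 1, 6),
      canopy_cover = runif(1), kcb = 1.05, root_depth = runif(1, 0.3, 1.5),
      irrigation = sample(c(0, 0, 25), 1),
      water_table_depth = sample(c(Inf, 1.5), 1),
      system = "rainfed"
    )
    st <- out$state
    fl <- out$fluxes
    inflow <- fl$rain_in + fl$irrigation_in + fl$capillary_in
    outflow <- fl$runoff_out + fl$evaporation_out + fl$transpiration_out +
      fl$deep_percolation_out
    after <- wfcrop:::soil_colour_totals(st)
    expect_equal(unname(after - before), unname(inflow - outflow),
                 tolerance = 1e-6)
    tab <- soil_state_table(st)
    f <- tab[tab$w_mm > 0, c("f_green", "f_blue_i", "f_blue_cr")]
    expect_true(all(f >= -1e-12 & f <= 1 + 1e-12))
    expect_equal(rowSums(f), rep(1, nrow(f)), tolerance = 1e-9)
  }
})

test_that("a dry profile with no inputs produces near-zero fluxes", {
  st <- soil_state(thick, hyd, initial = "dry")
  out <- step_water_balance(st, 0, 4, 0.5, 1.05, 1.0,
                            water_table_depth = Inf)
  fl <- out$fluxes
  expect_equal(sum(fl$rain_in) + sum(fl$irrigation_in) + sum(fl$capillary_in), 0)
  expect_equal(sum(fl$runoff_out) + sum(fl$deep_percolation_out), 0)
  expect_equal(sum(fl$evaporation_out) + sum(fl$transpiration_out), 0,
               tolerance = 1e-9)
})
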