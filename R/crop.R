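#' Crop parameter archetypes
#'
#' Loads the shipped archetype parameter table: an annual C3 cereal, a
#' low-sensitivity annual C4 cereal, paddy rice, a deciduous perennial and
#' an evergreen perennial. Columns are the full crop parameter set:
#' cardinal temperatures, canopy coefficients, rooting depths, normalized
#' water productivity, harvest index, stress thresholds, irrigation
#' trigger, growth habit and fresh-mass water content.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A tibble with one row per crop.
#' @export
crop_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crop_archetypes.csv", package = "wfcrop")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Daily growing degree days
#'
#' `GDD = max(0, (min(tmax, Tupp) + clamp(tmin, Tbase, Tupp)) / 2 - Tbase)`:
#' the daily maximum is capped at the upper temperature and the minimum is
#' clamped to the cardinal range before averaging.
#'
#' @param tmax,tmin Daily max/min air temperature, deg C (vectors allowed).
#' @param tbase,tupp Base and upper cardinal temperatures, deg C.
#' @return Degree days (deg C day), same length as `tmax`.
#' @export
daily_gdd <- function(tmax, tmin, tbase, tupp) {
  if (any(tmin > tmax + 1e-12)) abort("tmin > tmax")
  tx <- pmin(tmax, tupp)
  tn <- pmin(pmax(tmin, tbase), tupp)
  pmax(0, (tx + tn) / 2 - tbase)
}

#' Water stress coefficients from root-zone depletion
#'
#' Both coefficients are 1 while depletion Dr is below the crop's upper
#' threshold and fall linearly to 0 at total available water (wilting
#' point). Canopy expansion is the more sensitive process: its stress
#' engages at a lower depletion (0.7 of the stomatal threshold).
#'
#' @param dr Root-zone depletion below field capacity, mm.
#' @param taw Total available water in the root zone, mm (> 0).
#' @param p_up Depletion fraction at which stomatal stress begins.
#' @return `list(expansion, stomatal)`, each in \[0, 1\].
#' @export
water_stress_coefficients <- function(dr, taw, p_up) {
  if (taw <= 0) abort("TAW must be > 0")
  dr <- min(max(dr, 0), taw)
  ks_at <- function(p) {
    thr <- p * taw
    if (dr <= thr) 1 else max(0, 1 - (dr - thr) / (taw - thr))
  }
  list(expansion = ks_at(0.7 * p_up), stomatal = ks_at(p_up))
}

#' Canopy cover development
#'
#' Canopy cover as a closed-form function of accumulated effective thermal
#' time. Growth follows exponential expansion from `cc0`,
#' `CC = CC0 e^(CGC t)`, mirrored into an exponential approach to the
#' maximum cover `ccx` once half of `ccx` is reached; senescence is an
#' exponential decline with `cdc`. Water stress enters by scaling the
#' thermal time used for expansion (the caller accumulates
#' `gdd * ks_expansion`).
#'
#' @param t_growth Effective thermal time since emergence (deg C day,
#'   stress-scaled).
#' @param t_senescence Thermal time since the start of senescence, or 0.
#' @param cc0,ccx Initial and maximum canopy cover fractions.
#' @param cgc,cdc Canopy growth/decline coefficients per deg C day.
#' @return Canopy cover fraction in \[0, ccx\].
#' @export
canopy_cover_at <- function(t_growth, t_senescence, cc0, ccx, cgc, cdc) {
  cc <- if (t_senescence <= 0) {
    grow <- cc0 * exp(cgc * t_growth)
    if (grow <= ccx / 2) grow
    else ccx - 0.25 * (ccx^2 / cc0) * exp(-cgc * t_growth)
  } else {
    cc_sen0 <- canopy_cover_at(t_growth, 0, cc0, ccx, cgc, cdc)
    cc_sen0 * exp(-cdc * t_senescence)
  }
  min(max(cc, 0), ccx)
}

#' CO2 adjustment of water productivity
#'
#' A saturating multiplier on normalized water productivity, equal to 1 at
#' the reference concentration (369.41 ppm, year 2000):
#' `f = 1 + a (C - Cref) / (C - Cref + b)` for `C >= Cref` (and the
#' symmetric decline below). The sensitivity `a` is crop-class specific:
#' about +10% at +200 ppm for C3 crops, about +2% for C4.
#'
#' @param co2 Atmospheric CO2, ppm.
#' @param co2_sens Sensitivity parameter `a` (0.2 for C3, 0.04 for C4).
#' @param co2_ref Reference concentration, ppm.
#' @return Dimensionless multiplier.
#' @export
f_co2 <- function(co2, co2_sens = 0.2, co2_ref = 369.41) {
  d <- co2 - co2_ref
  1 + co2_sens * d / (abs(d) + 200)
}

#' Daily biomass increment from transpiration
#'
#' Above-ground dry biomass grows in proportion to normalized
#' transpiration: `dB = WP* f_CO2 (Tr / ET0)` (t/ha).
#'
#' @param tr Actual transpiration, mm.
#' @param et0 Reference evapotranspiration, mm (> 0).
#' @param wp_star Normalized water productivity, t/ha per unit `sum(Tr/ET0)`.
#' @param co2 Atmospheric CO2, ppm.
#' @param co2_sens CO2 sensitivity (see [f_co2()]).
#' @param co2_ref Reference CO2, ppm.
#' @return Biomass increment, t/ha.
#' @export
biomass_increment <- function(tr, et0, wp_star, co2 = 369.41,
                              co2_sens = 0.2, co2_ref = 369.41) {
  if (any(et0 <= 0)) abort("et0 must be > 0")
  wp_star * f_co2(co2, co2_sens, co2_ref) * (tr / et0)
}

#' Stress-adjusted yield at harvest
#'
#' Dry yield is biomass times a reference harvest index reduced by two
#' stress terms: pollination failure on flowering-window days whose maximum
#' temperature exceeded the critical threshold
#' (`f_heat = max(0.05, 1 - failed/window)`), and severe water stress
#' during yield formation (`f_water = 0.2 + 0.8 * mean Ks_stomatal`).
#'
#' @param biomass Accumulated dry biomass, t/ha.
#' @param hi0 Reference harvest index fraction.
#' @param heat_fail_days Flowering days with `tmax > Tcrit_heat`.
#' @param flowering_days Total days in the flowering window.
#' @param mean_ks_yield Mean stomatal stress coefficient during yield
#'   formation (1 = unstressed).
#' @return Dry yield, t/ha.
#' @export
yield_at_harvest <- function(biomass, hi0, heat_fail_days = 0,
                             flowering_days = 0, mean_ks_yield = 1) {
  f_heat <- if (flowering_days > 0) {
    max(0.05, 1 - heat_fail_days / flowering_days)
  } else 1
  f_water <- 0.2 + 0.8 * min(max(mean_ks_yield, 0), 1)
  biomass * hi0 * f_heat * f_water
}

# Stage boundaries as fractions of the maturity heat-unit requirement,
# shared by all archetypes.
WF_STAGE_FRACTIONS <- c(emergence = 0.05, max_canopy = 0.40,
                        senescence = 0.80, maturity = 1.00)
# Flowering / yield-formation windows on the same scale.
WF_FLOWERING_WINDOW <- c(0.40, 0.55)
WF_YIELD_WINDOW <- c(0.55, 0.90)

#' Calibrate heat-unit requirements to a reference calendar
#'
#' The maturity requirement for a grid cell is the mean cumulative GDD
#' between the reference planting and harvest days over the available
#' weather years; stage requirements are fixed fractions of it (emergence
#' 5%, maximum canopy 40%, senescence 80%, maturity 100%).
#'
#' @param weather Daily weather tibble with `year`, `doy`, `tmax`, `tmin`.
#' @param planting_doy,harvest_doy Reference calendar days of year; a
#'   harvest day before the planting day means the season crosses the year
#'   boundary (winter crops).
#' @param tbase,tupp Cardinal temperatures, deg C.
#' @return `list(gdd_maturity, stages)` where `stages` is a named vector of
#'   cumulative GDD thresholds, or `NULL` (cell non-viable) when no heat
#'   units accumulate.
#' @export
calibrate_heat_units <- function(weather, planting_doy, harvest_doy,
                                 tbase, tupp) {
  gdd <- daily_gdd(weather$tmax, weather$tmin, tbase, tupp)
  years <- sort(unique(weather$year))
  sums <- c()
  for (y in years) {
    if (harvest_doy >= planting_doy) {
      idx <- weather$year == y & weather$doy >= planting_doy &
        weather$doy <= harvest_doy
    } else {
      if (!(y + 1) %in% years) next
      idx <- (weather$year == y & weather$doy >= planting_doy) |
        (weather$year == y + 1 & weather$doy <= harvest_doy)
    }
    if (any(idx)) sums <- c(sums, sum(gdd[idx]))
  }
  if (!length(sums) || mean(sums) <= 0) return(NULL)
  maturity <- mean(sums)
  list(gdd_maturity = maturity, stages = WF_STAGE_FRACTIONS * maturity)
}

#' Realized season window under calendar-adjustment rules
#'
#' Emergence waits (up to 30 days past planting) for the top compartment
#' to hold enough moisture for germination; harvest occurs when the
#' maturity heat-unit requirement is met, capped at 1.15 times the
#' reference season length for annual crops (cold years may extend the
#' season up to that cap, warm years mature earlier). Evergreen perennials
#' are always harvested on 31 December.
#'
#' This helper computes the realized window from a daily GDD series and a
#' day-indexed moisture-adequacy flag; the season engine applies the same
#' rules day by day during simulation.
#'
#' @param gdd Daily GDD from the planting day onward.
#' @param seedbed_moist Logical vector (same indexing): is the seedbed
#'   moist enough for germination on that day?
#' @param gdd_maturity Maturity requirement, deg C day.
#' @param reference_length Reference season length, days.
#' @param max_extension Season cap as a multiple of the reference length.
#' @return `list(emergence_offset, harvest_offset, matured)` — day offsets
#'   from planting.
#' @export
adjust_calendar <- function(gdd, seedbed_moist, gdd_maturity,
                            reference_length, max_extension = 1.15) {
  n <- length(gdd)
  emerge <- which(seedbed_moist[seq_len(min(31, n))])[1]
  if (is.na(emerge)) emerge <- min(31, n)
  cap <- min(n, ceiling(max_extension * reference_length))
  cum <- cumsum(gdd)
  cum <- cum - if (emerge > 1) cum[emerge - 1] else 0
  reached <- which(seq_len(n) >= emerge & cum >= gdd_maturity)[1]
  if (!is.na(reached) && reached <= cap) {
    list(emergence_offset = emerge, harvest_offset = reached, matured = TRUE)
  } else {
    list(emergence_offset = emerge, harvest_offset = cap, matured = FALSE)
  }
}

# Rooting depth at a given development stage: linear in GDD up to the
# max-canopy stage for annuals; perennials keep their maximum depth.
root_depth_at <- function(gdd_cum, zmin, zmax, gdd_maxroot, habit) {
  if (habit != "annual") return(zmax)
  if (gdd_maxroot <= 0) return(zmax)
  zmin + (zmax - zmin) * min(1, gdd_cum / gdd_maxroot)
}
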