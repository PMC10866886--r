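#' Simulate one (cell, crop, system) over all years
#'
#' Runs the coupled daily loop: groundwater interpolation, irrigation
#' decision, the colour-traced water-balance step, heat-unit phenology,
#' canopy development, biomass accumulation and stress bookkeeping. The
#' simulation starts two warm-up years before the first reported year
#' (warm-up harvests are discarded) and continues through fallow periods
#' (a static cover crop: CC 0.30, Kcb 0.60, 0.3 m rooting) so soil
#' moisture carries over between seasons. Annual crops yield one season
#' per harvest year; perennials yield one result per calendar year with
#' crop water use accumulated over the entire year (evergreens harvest on
#' 31 December). Seasons still in progress when the simulation ends are
#' dropped.
#'
#' @param weather Daily weather tibble for the cell including an `et0`
#'   column (see [reference_et0()]).
#' @param crop_pars One row of [crop_parameters()] (list or one-row tibble).
#' @param policy Matching row of [irrigation_policies()].
#' @param system `"rainfed"` or `"irrigated"`.
#' @param hydraulics From [soil_hydraulics()].
#' @param thicknesses From [soil_profile()].
#' @param gw_daily Daily groundwater depth vector (m), `NULL` for none.
#' @param co2 Tibble `year`, `ppm`; `NULL` for the reference concentration.
#' @param report_years Calendar years to report (everything earlier is
#'   warm-up).
#' @param initial Initial soil water: `"fc"` or `"dry"`.
#' @param details If `TRUE`, return
#'   `list(seasons, ledger, final_state, daily)` where `ledger` holds
#'   cumulative per-colour inflows/outflows and storages for conservation
#'   checks.
#' @return A tibble of per-season results (one row per harvest year).
#' @export
run_cell <- function(weather, crop_pars, policy, system, hydraulics,
                     thicknesses, gw_daily = NULL, co2 = NULL,
                     report_years, initial = "fc", details = FALSE) {
  p <- as.list(crop_pars)
  pol <- as.list(policy)
  is_rice <- isTRUE(p$is_rice)
  bund <- if (is_rice) pol$bund_height_mm else 0
  fw <- if (identical(system, "irrigated")) pol$wetted_fraction else 1
  irrigated <- identical(system, "irrigated")

  cal <- calibrate_heat_units(weather, p$planting_doy, p$harvest_doy,
                              p$tbase, p$tupp)
  if (is.null(cal)) {
    out <- season_empty()
    if (details) return(list(seasons = out, reason = "non-viable cell"))
    return(out)
  }
  stages <- cal$stages
  maturity <- cal$gdd_maturity
  ref_len <- (p$harvest_doy - p$planting_doy) %% 365
  if (ref_len == 0) ref_len <- 365
  season_cap <- ceiling(1.15 * ref_len)

  # Deciduous bud break requirement: mean 10-day running GDD sum ending at
  # the reference bud-break (planting) day over the weather years.
  budbreak_req <- NULL
  if (p$habit == "deciduous_perennial") {
    g <- daily_gdd(weather$tmax, weather$tmin, p$tbase, p$tupp)
    run10 <- as.numeric(stats::filter(g, rep(1, 10), sides = 1))
    at <- which(weather$doy == p$planting_doy)
    budbreak_req <- mean(run10[at], na.rm = TRUE)
  }

  n <- nrow(weather)
  precip <- weather$precip; et0v <- weather$et0
  tmaxv <- weather$tmax; tminv <- weather$tmin
  yearv <- weather$year; doyv <- weather$doy
  gddv <- daily_gdd(tmaxv, tminv, p$tbase, p$tupp)
  co2v <- if (is.null(co2)) rep(369.41, n) else {
    co2$ppm[match(yearv, co2$year)]
  }
  gwv <- if (is.null(gw_daily)) rep(Inf, n) else gw_daily

  state <- soil_state(thicknesses, hydraulics, initial = initial)
  zero3 <- setNames(numeric(3), WF_COLOURS)

  perennial <- p$habit != "annual"
  evergreen <- p$habit == "evergreen_perennial"
  deciduous <- p$habit == "deciduous_perennial"

  phase <- if (evergreen) "growing" else "fallow"
  gdd_cum <- 0; t_growth <- 0; t_sen <- 0; biomass <- 0
  waiting_since <- NA_integer_; planting_i <- NA_integer_
  emergence_doy <- NA_integer_; emergence_i <- NA_integer_
  cwu <- zero3; irr_total <- 0
  flower_days <- 0L; flower_fail <- 0L; ks_sum <- 0; ks_n <- 0L
  run10_gdd <- numeric(0)

  seasons <- list()
  ledger_in <- zero3; ledger_out <- zero3; ledger_et <- zero3
  ledger_irr <- 0
  storage0 <- soil_colour_totals(state)

  germination_ok <- function(st) {
    w1 <- sum(st$M[, 1])
    w1 >= st$wp_mm[1] + 0.25 * (st$fc_mm[1] - st$wp_mm[1])
  }

  reset_season <- function() {
    gdd_cum <<- 0; t_growth <<- 0; t_sen <<- 0; biomass <<- 0
    cwu <<- zero3; irr_total <<- 0
    flower_days <<- 0L; flower_fail <<- 0L; ks_sum <<- 0; ks_n <<- 0L
  }

  year_cwu <- zero3  # perennials: calendar-year accumulation
  year_irr <- 0
  year_harvest <- NULL

  for (i in seq_len(n)) {
    doy <- doyv[i]; yr <- yearv[i]

    # --- Phenology bookkeeping before the water step -----------------
    if (!perennial) {
      if (phase == "fallow" && doy == p$planting_doy) {
        phase <- "waiting"; waiting_since <- i; planting_i <- i
      }
      if (phase == "waiting") {
        if (germination_ok(state) || (i - waiting_since) >= 30) {
          phase <- "growing"; emergence_doy <- doy; emergence_i <- i
          reset_season()
        }
      }
    } else if (deciduous) {
      if (phase == "fallow" && doy >= 32) {
        run10 <- sum(gddv[max(1, i - 9):i])
        if (run10 >= budbreak_req && doy <= 240) {
          phase <- "growing"; emergence_doy <- doy; emergence_i <- i
          reset_season()
        }
      }
    }

    growing <- phase == "growing"
    if (growing) {
      frac <- gdd_cum / maturity
      cc <- if (evergreen) {
        p$ccx
      } else {
        base_cc <- canopy_cover_at(t_growth, t_sen, p$cc0, p$ccx, p$cgc, p$cdc)
        if (deciduous) max(base_cc, p$cc_min_leafless) else base_cc
      }
      z <- root_depth_at(gdd_cum, p$zmin, p$zmax, stages[["max_canopy"]], p$habit)
      kcb <- p$kcb
    } else {
      cc <- if (deciduous) p$cc_min_leafless else 0.30
      kcb <- 0.60
      z <- if (perennial) p$zmax else 0.30
      frac <- 0
    }

    # --- Irrigation decision (previous-evening soil state) -----------
    irr <- 0
    if (irrigated && growing) {
      rz <- root_zone_status(state, z)
      irr <- if (is_rice) {
        irrigation_decision(rz$dr, rz$taw, NA, rice = TRUE, state = state,
                            root_depth = z)
      } else {
        irrigation_decision(rz$dr, max(rz$taw, 1e-9), pol$trigger_depletion)
      }
    }

    # --- Water balance step ------------------------------------------
    st <- step_water_balance(
      state, precip[i], et0v[i], cc, kcb, z, irrigation = irr,
      water_table_depth = gwv[i], system = system, crop_is_rice = is_rice,
      p_up = if (growing) p$p_up else 0.5, fw_evap = if (growing) fw else 1,
      bund_height = bund
    )
    state <- st$state
    fl <- st$fluxes
    ledger_in <- ledger_in + fl$rain_in + fl$irrigation_in + fl$capillary_in
    ledger_out <- ledger_out + fl$runoff_out + fl$evaporation_out +
      fl$transpiration_out + fl$deep_percolation_out
    ledger_et <- ledger_et + fl$evaporation_out + fl$transpiration_out
    ledger_irr <- ledger_irr + irr

    if (growing) {
      et_col <- fl$evaporation_out + fl$transpiration_out
      cwu <- cwu + et_col
      irr_total <- irr_total + irr
      if (perennial) { year_cwu <- year_cwu + et_col; year_irr <- year_irr + irr }
      tr <- sum(fl$transpiration_out)
      if (et0v[i] > 0) {
        biomass <- biomass + biomass_increment(tr, et0v[i], p$wp_star,
                                               co2v[i], p$co2_sens)
      }
      g <- gddv[i]
      gdd_cum <- gdd_cum + g
      if (gdd_cum < stages[["senescence"]]) {
        t_growth <- t_growth + g * st$ks_expansion
      } else {
        t_sen <- t_sen + g
      }
      frac2 <- gdd_cum / maturity
      if (frac < WF_FLOWERING_WINDOW[2] && frac2 >= WF_FLOWERING_WINDOW[1]) {
        flower_days <- flower_days + 1L
        if (tmaxv[i] > p$tcrit_heat) flower_fail <- flower_fail + 1L
      }
      if (frac < WF_YIELD_WINDOW[2] && frac2 >= WF_YIELD_WINDOW[1]) {
        ks_sum <- ks_sum + st$ks_stomatal; ks_n <- ks_n + 1L
      }
    } else if (perennial) {
      year_cwu <- year_cwu + fl$evaporation_out + fl$transpiration_out
    }

    # --- Harvest checks ----------------------------------------------
    if (growing && !evergreen) {
      matured <- gdd_cum >= maturity
      capped <- !perennial && !is.na(planting_i) &&
        (i - planting_i + 1) >= season_cap
      deciduous_end <- deciduous && doy >= 334
      if (matured || capped || deciduous_end) {
        mean_ks <- if (ks_n > 0) ks_sum / ks_n else 1
        dy <- yield_at_harvest(biomass, p$hi0, flower_fail, flower_days, mean_ks)
        if (!perennial) {
          seasons[[length(seasons) + 1L]] <- list(
            harvest_year = yr, system = system, crop = p$crop,
            cwu_green = cwu[["green"]], cwu_blue_cr = cwu[["blue_cr"]],
            cwu_blue_i = cwu[["blue_i"]], dry_yield = dy,
            irrigation_mm = irr_total,
            emergence_doy = emergence_doy, harvest_doy = doy,
            planting_year = yearv[planting_i],
            season_days = i - planting_i + 1L, matured = matured
          )
        } else {
          year_harvest <- list(dy = dy, harvest_doy = doy,
                               emergence_doy = emergence_doy, matured = matured)
        }
        phase <- "fallow"
      }
    }

    # Perennials report once per calendar year on 31 December.
    if (perennial && doy == 365) {
      if (evergreen) {
        mean_ks <- if (ks_n > 0) ks_sum / ks_n else 1
        dy <- yield_at_harvest(biomass, p$hi0, flower_fail, flower_days, mean_ks)
        year_harvest <- list(dy = dy, harvest_doy = 365L,
                             emergence_doy = 1L, matured = TRUE)
      }
      seasons[[length(seasons) + 1L]] <- list(
        harvest_year = yr, system = system, crop = p$crop,
        cwu_green = year_cwu[["green"]], cwu_blue_cr = year_cwu[["blue_cr"]],
        cwu_blue_i = year_cwu[["blue_i"]],
        dry_yield = if (is.null(year_harvest)) 0 else year_harvest$dy,
        irrigation_mm = year_irr,
        emergence_doy = if (is.null(year_harvest)) NA_integer_ else
          year_harvest$emergence_doy,
        harvest_doy = if (is.null(year_harvest)) NA_integer_ else
          year_harvest$harvest_doy,
        planting_year = yr, season_days = 365L,
        matured = !is.null(year_harvest) && year_harvest$matured
      )
      year_cwu <- zero3; year_irr <- 0; year_harvest <- NULL
      if (evergreen) reset_season()
    }
  }

  out <- if (length(seasons)) {
    dplyr::bind_rows(lapply(seasons, as_tibble))
  } else season_empty()
  out <- out[out$harvest_year %in% report_years, , drop = FALSE]

  if (details) {
    storage1 <- soil_colour_totals(state)
    list(seasons = out,
         ledger = tibble(colour = WF_COLOURS,
                         inflow_mm = as.numeric(ledger_in),
                         outflow_mm = as.numeric(ledger_out),
                         et_mm = as.numeric(ledger_et),
                         storage_start_mm = as.numeric(storage0),
                         storage_end_mm = as.numeric(storage1)),
         irrigation_applied_mm = ledger_irr,
         final_state = state)
  } else {
    out
  }
}

season_empty <- function() {
  tibble(harvest_year = integer(), system = character(), crop = character(),
         cwu_green = numeric(), cwu_blue_cr = numeric(),
         cwu_blue_i = numeric(), dry_yield = numeric(),
         irrigation_mm = numeric(), emergence_doy = integer(),
         harvest_doy = integer(), planting_year = integer(),
         season_days = integer(), matured = logical())
}

#' Harvest-year attribution
#'
#' All crop water use and yield of a season are reported under the
#' calendar year of harvest, even when planting happened the year before
#' (winter crops). Perennials report under the calendar year (evergreens
#' harvest on 31 December).
#'
#' @param planting_year,harvest_year Calendar years.
#' @return The reporting year (the harvest year).
#' @export
attribute_to_harvest_year <- function(planting_year, harvest_year) {
  harvest_year
}

#' Run the full simulation over a synthetic world
#'
#' Simulates every (coarse cell, crop, system) combination with positive
#' harvested area and binds the per-season results.
#'
#' @param world A `wf_world` from [generate_world()].
#' @return A tibble of seasons with `cell` prepended.
#' @export
wf_simulate <- function(world) {
  combos <- world$areas %>%
    group_by(.data$coarse_cell, .data$crop, .data$system) %>%
    summarise(area_ha = sum(.data$area_ha), .groups = "drop") %>%
    filter(.data$area_ha > 0)

  gw_by_cell <- split(world$groundwater, world$groundwater$cell)

  purrr::pmap_dfr(
    combos[, c("coarse_cell", "crop", "system")],
    function(coarse_cell, crop, system) {
      info <- world$cells[world$cells$cell == coarse_cell, ]
      p <- world$crops[world$crops$crop == crop, ]
      pol <- world$policies[world$policies$crop == crop, ]
      hyd <- soil_hydraulics(info$texture)
      thick <- soil_profile(p$profile)
      gw_daily <- daily_groundwater_depth(gw_by_cell[[as.character(coarse_cell)]],
                                          world$config$years)
      res <- run_cell(world$weather[[as.character(coarse_cell)]], p, pol,
                      system, hyd, thick, gw_daily = gw_daily,
                      co2 = world$co2, report_years = world$report_years)
      if (nrow(res)) dplyr::mutate(res, cell = coarse_cell, .before = 1)
      else res
    }
  )
}
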