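#' Soil hydraulic parameter sets by texture class
#'
#' A small pedotransfer table mapping texture classes to volumetric water
#' contents at saturation, field capacity and wilting point, the daily
#' drainage coefficient `tau`, the SCS curve number `cn`, and readily
#' evaporable water `rew` (mm).
#'
#' @param texture One of `"sandy_loam"`, `"loam"`, `"clay_loam"`.
#' @return A list with elements `theta_sat`, `theta_fc`, `theta_wp`, `tau`,
#'   `cn`, `rew`, `texture`.
#' @export
soil_hydraulics <- function(texture = c("loam", "sandy_loam", "clay_loam")) {
  texture <- match.arg(texture)
  tab <- list(
    sandy_loam = list(theta_sat = 0.41, theta_fc = 0.22, theta_wp = 0.10,
                      tau = 0.80, cn = 72, rew = 7),
    loam       = list(theta_sat = 0.46, theta_fc = 0.29, theta_wp = 0.13,
                      tau = 0.60, cn = 78, rew = 9),
    clay_loam  = list(theta_sat = 0.50, theta_fc = 0.35, theta_wp = 0.19,
                      tau = 0.40, cn = 83, rew = 10)
  )
  h <- tab[[texture]]
  h$texture <- texture
  h
}

#' Soil profile discretisation
#'
#' The default deep profile is 3 m in eight compartments with thicknesses
#' between 0.1 and 0.7 m (thin near the surface, thick at depth); the
#' shallow variant for shallow-rooted crops is 2 m in seven compartments.
#'
#' @param variant `"deep"` (3 m, 8 compartments) or `"shallow"` (2 m, 7).
#' @return Numeric vector of compartment thicknesses (m).
#' @export
soil_profile <- function(variant = c("deep", "shallow")) {
  variant <- match.arg(variant)
  switch(variant,
    deep    = c(0.10, 0.15, 0.25, 0.30, 0.40, 0.55, 0.55, 0.70),
    shallow = c(0.10, 0.15, 0.25, 0.30, 0.35, 0.40, 0.45)
  )
}

#' Construct a colour-traced soil water state
#'
#' Water storage is held per compartment as three colour masses (green,
#' blue from irrigation, blue from capillary rise); colour fractions are
#' derived, so mass conservation per colour is structural. A surface
#' ponding store (for flooded rice) is colour-traced the same way.
#'
#' @param thicknesses Compartment thicknesses (m), see [soil_profile()].
#' @param hydraulics A list from [soil_hydraulics()].
#' @param initial `"dry"` (wilting point), `"fc"` (field capacity), or a
#'   numeric volumetric water content.
#' @param colour Colour of the initial water (default `"green"`).
#' @return An object of class `wf_soil_state`.
#' @export
soil_state <- function(thicknesses, hydraulics, initial = "fc", colour = "green") {
  n <- length(thicknesses)
  theta0 <- if (identical(initial, "dry")) hydraulics$theta_wp
            else if (identical(initial, "fc")) hydraulics$theta_fc
            else as.numeric(initial)
  w0 <- theta0 * thicknesses * 1000
  M <- matrix(0, nrow = 3, ncol = n, dimnames = list(WF_COLOURS, NULL))
  M[match(colour, WF_COLOURS), ] <- w0
  structure(list(
    thicknesses = thicknesses,
    hyd = hydraulics,
    M = M,
    pond = setNames(numeric(3), WF_COLOURS),
    sat_mm = hydraulics$theta_sat * thicknesses * 1000,
    fc_mm  = hydraulics$theta_fc  * thicknesses * 1000,
    wp_mm  = hydraulics$theta_wp  * thicknesses * 1000
  ), class = "wf_soil_state")
}

#' @export
print.wf_soil_state <- function(x, ...) {
  cat("<wf_soil_state> ", length(x$thicknesses), " compartments, ",
      round(sum(x$thicknesses), 2), " m, total water ",
      round(sum(x$M) + sum(x$pond), 1), " mm\n", sep = "")
  invisible(x)
}

#' Per-compartment storage and colour fractions
#'
#' @param state A `wf_soil_state`.
#' @return A tibble with one row per compartment: `compartment`,
#'   `thickness_m`, `w_mm`, `f_green`, `f_blue_i`, `f_blue_cr`.
#' @export
soil_state_table <- function(state) {
  w <- colSums(state$M)
  f <- sweep(state$M, 2, ifelse(w > 0, w, 1), "/")
  tibble(
    compartment = seq_along(w),
    thickness_m = state$thicknesses,
    w_mm = w,
    f_green = ifelse(w > 0, f["green", ], NA_real_),
    f_blue_i = ifelse(w > 0, f["blue_i", ], NA_real_),
    f_blue_cr = ifelse(w > 0, f["blue_cr", ], NA_real_)
  )
}

# Total stored water per colour (soil + pond), mm.
soil_colour_totals <- function(state) rowSums(state$M) + state$pond

#' Total soil water (mm), including surface ponding
#' @param state A `wf_soil_state`.
#' @export
soil_water_total <- function(state) sum(state$M) + sum(state$pond)

#' Curve-number surface runoff
#'
#' Daily SCS curve-number runoff with the standard 20% initial abstraction:
#' `S = 254 (100/CN - 1)`, runoff is zero for `P <= 0.2 S`, otherwise
#' `(P - 0.2 S)^2 / (P + 0.8 S)`. On bunded (flooded rice) fields runoff is
#' suppressed until the ponded water exceeds the bund height; only the
#' excess spills.
#'
#' @param precip Daily precipitation reaching the surface, mm.
#' @param cn Curve number in (0, 100).
#' @param bund_height Bund height, mm (300 for rice); 0 disables bunds.
#' @param ponding Current ponded depth, mm (bunded fields only).
#' @return Runoff depth, mm.
#' @export
curve_number_runoff <- function(precip, cn, bund_height = 0, ponding = 0) {
  if (precip < 0) abort("precip must be >= 0")
  if (bund_height > 0) {
    return(max(0, ponding + precip - bund_height))
  }
  if (cn <= 0 || cn >= 100) abort("curve number must lie in (0, 100)")
  s <- 254 * (100 / cn - 1)
  if (precip <= 0.2 * s) 0 else (precip - 0.2 * s)^2 / (precip + 0.8 * s)
}

#' Mix an inflow of one colour into a compartment
#'
#' Incoming water mixes completely with the water already stored at that
#' depth: the storage increases by `amount` and the colour fractions update
#' by mass. Overfilling beyond saturation is an error here — callers route
#' excess to the next store instead of clipping.
#'
#' @param state A `wf_soil_state`.
#' @param compartment Compartment index.
#' @param amount Inflow, mm (>= 0).
#' @param colour `"green"`, `"blue_i"` or `"blue_cr"`.
#' @return The updated state.
#' @export
mix_inflow <- function(state, compartment, amount, colour) {
  if (amount < 0) abort("inflow amount must be >= 0")
  ci <- match(colour, WF_COLOURS)
  if (is.na(ci)) abort("unknown water colour")
  w <- sum(state$M[, compartment])
  if (w + amount > state$sat_mm[compartment] + 1e-9) {
    abort("inflow exceeds saturation; route excess to the next store",
          class = "wf_overfill")
  }
  state$M[ci, compartment] <- state$M[ci, compartment] + amount
  state
}

# Remove `amount` mm from a compartment, carrying its current colour mix.
# Returns list(state, removed = 3-vector).
st_remove <- function(state, compartment, amount) {
  w <- sum(state$M[, compartment])
  amount <- min(amount, w)
  if (w <= 0 || amount <= 0) {
    return(list(state = state, removed = setNames(numeric(3), WF_COLOURS)))
  }
  removed <- state$M[, compartment] * (amount / w)
  state$M[, compartment] <- state$M[, compartment] - removed
  list(state = state, removed = removed)
}

# Infiltrate `amount` of a single colour from the surface downward, filling
# compartments to saturation in order. Returns list(state, leftover).
infiltrate_cascade <- function(state, amount, colour, log_env = NULL) {
  ci <- match(colour, WF_COLOURS)
  n <- ncol(state$M)
  for (i in seq_len(n)) {
    if (amount <= 0) break
    room <- state$sat_mm[i] - sum(state$M[, i])
    take <- min(room, amount)
    if (take > 0) {
      state$M[ci, i] <- state$M[ci, i] + take
      log_event(log_env, colour, paste0("c", i), take)
      amount <- amount - take
    }
  }
  list(state = state, leftover = amount)
}

#' Drain excess water through the compartment cascade
#'
#' Water above field capacity drains at rate `tau` per day into the
#' compartment below (carrying the donor's colour mix); drainage from the
#' bottom compartment leaves as deep percolation. No compartment ends above
#' saturation: inflow to a full receiver is held back.
#'
#' @param state A `wf_soil_state`.
#' @return `list(state, percolation)` where `percolation` is a named
#'   3-vector of deep percolation by colour (mm).
#' @export
drain <- function(state) {
  drain_logged(state, NULL)
}

drain_logged <- function(state, log_env, tau = state$hyd$tau) {
  M <- state$M
  n <- ncol(M)
  fc <- state$fc_mm; sat <- state$sat_mm
  perc <- setNames(numeric(3), WF_COLOURS)
  wtot <- colSums(M)
  for (i in seq_len(n)) {
    excess <- wtot[i] - fc[i]
    if (excess <= 1e-12) next
    d <- tau * excess
    if (i < n) {
      d <- min(d, max(sat[i + 1] - wtot[i + 1], 0))
      if (d <= 0) next
      mv <- M[, i] * (d / wtot[i])
      M[, i] <- M[, i] - mv
      M[, i + 1] <- M[, i + 1] + mv
      wtot[i] <- wtot[i] - d
      wtot[i + 1] <- wtot[i + 1] + d
      log_event(log_env, paste0("c", i), paste0("c", i + 1), d)
    } else {
      mv <- M[, i] * (d / wtot[i])
      M[, i] <- M[, i] - mv
      perc <- perc + mv
      log_event(log_env, paste0("c", i), "perc", d)
    }
  }
  state$M <- M
  list(state = state, percolation = perc)
}

#' Capillary rise from a shallow water table
#'
#' Upward flux from shallow groundwater into the lowest compartments,
#' counted as blue water from capillary rise. Applies only to rainfed
#' crops — irrigated fields are assumed not to draw on groundwater — with
#' flooded rice as the exception. The flux is zero for water tables deeper
#' than 4 m, decreases linearly with depth above that, and is gated by the
#' sub-field-capacity deficit of the two deepest compartments that lie
#' above the water table (the bottom of the unsaturated zone). Where the raw
#' water table reaches the surface the effective depth is 1 m (soils are
#' assumed drained to 1 m to avoid aeration stress).
#'
#' @param state A `wf_soil_state`.
#' @param water_table_depth Depth to groundwater, m (> 0 allowed; values
#'   below 1 m are raised to 1 m).
#' @param system `"rainfed"` or `"irrigated"`.
#' @param crop_is_rice Logical; irrigated rice still receives capillary rise.
#' @param cr_max Maximum flux at 1 m depth, mm/day.
#' @return `list(state, flux)` with `flux` the applied inflow (mm).
#' @export
capillary_rise <- function(state, water_table_depth, system = "rainfed",
                           crop_is_rice = FALSE, cr_max = 2) {
  capillary_rise_logged(state, water_table_depth, system, crop_is_rice, cr_max, NULL)
}

capillary_rise_logged <- function(state, water_table_depth, system,
                                  crop_is_rice, cr_max, log_env) {
  if (water_table_depth < 0) abort("water table depth must be >= 0")
  if (identical(system, "irrigated") && !crop_is_rice) {
    return(list(state = state, flux = 0))
  }
  d <- max(water_table_depth, 1)
  if (d > 4) return(list(state = state, flux = 0))
  max_flux <- cr_max * (4 - d) / 3
  # the rise wets the deepest compartments of the unsaturated zone, i.e.
  # those lying fully above the (effective) water table
  bounds <- cumsum(state$thicknesses)
  above <- which(bounds <= d + 1e-9)
  if (!length(above)) above <- 1L
  lowest <- utils::tail(above, 2)
  deficit <- sum(pmax(state$fc_mm[lowest] - colSums(state$M)[lowest], 0))
  flux <- min(max_flux, deficit)
  if (flux <= 0) return(list(state = state, flux = 0))
  remaining <- flux
  for (i in rev(lowest)) {  # fill from the bottom up
    room <- max(state$fc_mm[i] - sum(state$M[, i]), 0)
    take <- min(room, remaining)
    if (take > 0) {
      state$M["blue_cr", i] <- state$M["blue_cr", i] + take
      log_event(log_env, "blue_cr", paste0("c", i), take)
      remaining <- remaining - take
    }
  }
  list(state = state, flux = flux - remaining)
}

#' Root-zone water status
#'
#' Total available water (TAW, between field capacity and wilting point),
#' current depletion Dr relative to field capacity, and per-compartment
#' root-zone overlap weights for a given rooting depth.
#'
#' @param state A `wf_soil_state`.
#' @param root_depth Rooting depth, m.
#' @return `list(taw, dr, weights)` (mm, mm, vector).
#' @export
root_zone_status <- function(state, root_depth) {
  bounds <- cumsum(c(0, state$thicknesses))
  over <- pmax(pmin(bounds[-1], root_depth) - bounds[-length(bounds)], 0)
  frac <- over / state$thicknesses
  w <- colSums(state$M)
  taw <- sum(frac * (state$fc_mm - state$wp_mm))
  dr <- max(0, sum(frac * (state$fc_mm - w)))
  list(taw = taw, dr = dr, weights = frac)
}

#' Extract soil evaporation and transpiration with colour tracing
#'
#' Evaporation is drawn from the top compartment under two-stage drying:
#' energy-limited while the top-compartment depletion is within the readily
#' evaporable water (REW), then at a linearly falling rate until the
#' storage reaches wilting point. Transpiration is drawn from root-zone
#' compartments in proportion to the root-overlap weights, limited per
#' compartment by water above wilting point. Every millimetre removed
#' carries its donor compartment's current colour mix.
#'
#' @param state A `wf_soil_state`.
#' @param evap_demand Potential soil evaporation, mm.
#' @param transp_demand Transpiration demand, mm.
#' @param root_weights Per-compartment root overlap fractions (see
#'   [root_zone_status()]).
#' @return `list(state, evaporation, transpiration, evap_deficit,
#'   transp_deficit)`; flux components are named 3-vectors (mm).
#' @export
extract_evapotranspiration <- function(state, evap_demand, transp_demand,
                                       root_weights) {
  extract_et_logged(state, evap_demand, transp_demand, root_weights, NULL)
}

extract_et_logged <- function(state, evap_demand, transp_demand,
                              root_weights, log_env) {
  if (evap_demand < 0 || transp_demand < 0) abort("ET demands must be >= 0")
  evap <- setNames(numeric(3), WF_COLOURS)
  transp <- setNames(numeric(3), WF_COLOURS)

  # Evaporation: pond first (at full demand), then top compartment, two-stage.
  e_left <- evap_demand
  pond_tot <- sum(state$pond)
  if (pond_tot > 0 && e_left > 0) {
    take <- min(pond_tot, e_left)
    rem <- state$pond * (take / pond_tot)
    state$pond <- state$pond - rem
    evap <- evap + rem
    log_event(log_env, "pond", "evap", take)
    e_left <- e_left - take
  }
  if (e_left > 0) {
    w1 <- sum(state$M[, 1])
    tew <- state$fc_mm[1] - state$wp_mm[1]
    de <- max(0, state$fc_mm[1] - w1)
    rew <- min(state$hyd$rew, tew)
    kr <- if (de <= rew) 1 else max(0, (tew - de) / max(tew - rew, 1e-9))
    avail <- max(0, w1 - state$wp_mm[1])
    take <- min(kr * e_left, avail)
    if (take > 0) {
      out <- st_remove(state, 1, take)
      state <- out$state
      evap <- evap + out$removed
      log_event(log_env, "c1", "evap", take)
    }
    e_left <- e_left - take
  }

  # Transpiration: allocate demand over root-zone compartments by weight,
  # redistributing unmet demand to compartments with remaining supply.
  t_left <- transp_demand
  if (t_left > 0 && sum(root_weights) > 0) {
    M <- state$M
    wtot <- colSums(M)
    avail <- pmax(wtot - state$wp_mm, 0)
    active <- root_weights > 0 & avail > 1e-12
    for (pass in 1:4) {
      if (t_left <= 1e-12 || !any(active)) break
      wsum <- sum(root_weights[active])
      for (i in which(active)) {
        take <- min(t_left * root_weights[i] / wsum, avail[i])
        if (take > 0) {
          mv <- M[, i] * (take / wtot[i])
          M[, i] <- M[, i] - mv
          wtot[i] <- wtot[i] - take
          transp <- transp + mv
          log_event(log_env, paste0("c", i), "transp", take)
          avail[i] <- avail[i] - take
        }
      }
      t_left <- transp_demand - sum(transp)
      active <- root_weights > 0 & avail > 1e-12
    }
    state$M <- M
  }

  list(state = state,
       evaporation = evap,
       transpiration = transp,
       evap_deficit = max(0, e_left),
       transp_deficit = max(0, t_left))
}

#' One daily step of the colour-traced vertical water balance
#'
#' Applies, in fixed order: capillary rise, rainfall partition into runoff
#' and infiltration, irrigation infiltration (or pond top-up for flooded
#' rice), drainage, then evaporation and transpiration extraction. All
#' fluxes are returned split by water colour; mass is conserved per colour.
#'
#' @param state A `wf_soil_state`.
#' @param precip Rainfall, mm.
#' @param et0 Reference evapotranspiration, mm.
#' @param canopy_cover Canopy cover fraction in \[0, 1\].
#' @param kcb Basal transpiration coefficient.
#' @param root_depth Rooting depth, m.
#' @param irrigation Irrigation application, mm (colour blue_i).
#' @param water_table_depth Depth to groundwater, m (`Inf` for none).
#' @param system `"rainfed"` or `"irrigated"`.
#' @param crop_is_rice Logical; enables bunds/ponding behaviour.
#' @param p_up Depletion fraction at which stomatal water stress begins.
#' @param fw_evap Wetted-surface fraction scaling soil evaporation (drip
#'   irrigation wets only part of the surface).
#' @param bund_height Bund height, mm (default 300 for rice, else 0).
#' @param log Keep an event log of all water movements (for the parcel
#'   oracle and debugging); slows the step down.
#' @return `list(state, fluxes, ks_stomatal)`; `fluxes` is a list of named
#'   3-vectors: `rain_in`, `irrigation_in`, `capillary_in`, `runoff_out`,
#'   `evaporation_out`, `transpiration_out`, `deep_percolation_out`.
#' @export
step_water_balance <- function(state, precip, et0, canopy_cover, kcb,
                               root_depth, irrigation = 0,
                               water_table_depth = Inf,
                               system = "rainfed", crop_is_rice = FALSE,
                               p_up = 0.5, fw_evap = 1,
                               bund_height = if (crop_is_rice) 300 else 0,
                               log = FALSE) {
  if (precip < 0 || irrigation < 0) abort("precip and irrigation must be >= 0")
  log_env <- if (log) new.env() else NULL
  if (log) log_env$events <- list()
  zero <- setNames(numeric(3), WF_COLOURS)
  fl <- list(rain_in = zero, irrigation_in = zero, capillary_in = zero,
             runoff_out = zero, evaporation_out = zero,
             transpiration_out = zero, deep_percolation_out = zero)

  # 1. Capillary rise
  if (is.finite(water_table_depth)) {
    cr <- capillary_rise_logged(state, water_table_depth, system,
                                crop_is_rice, 2, log_env)
    state <- cr$state
    fl$capillary_in["blue_cr"] <- cr$flux
  }

  # 2. Rainfall: runoff vs infiltration (or pond on bunded fields)
  if (precip > 0) {
    fl$rain_in["green"] <- precip
    if (bund_height > 0) {
      state$pond["green"] <- state$pond["green"] + precip
      log_event(log_env, "green", "pond", precip)
      spill <- sum(state$pond) - bund_height
      if (spill > 0) {
        ptot <- sum(state$pond)
        rem <- state$pond * (spill / ptot)
        state$pond <- state$pond - rem
        fl$runoff_out <- fl$runoff_out + rem
        log_event(log_env, "pond", "runoff", spill)
      }
    } else {
      ro <- curve_number_runoff(precip, state$hyd$cn)
      if (ro > 0) {
        fl$runoff_out["green"] <- fl$runoff_out["green"] + ro
        log_event(log_env, "green", "runoff", ro)
      }
      inf <- infiltrate_cascade(state, precip - ro, "green", log_env)
      state <- inf$state
      if (inf$leftover > 0) {  # profile saturated: excess cannot infiltrate
        fl$runoff_out["green"] <- fl$runoff_out["green"] + inf$leftover
        log_event(log_env, "green", "runoff", inf$leftover)
      }
    }
  }

  # 3. Irrigation
  if (irrigation > 0) {
    fl$irrigation_in["blue_i"] <- irrigation
    if (bund_height > 0) {
      state$pond["blue_i"] <- state$pond["blue_i"] + irrigation
      log_event(log_env, "blue_i", "pond", irrigation)
    } else {
      inf <- infiltrate_cascade(state, irrigation, "blue_i", log_env)
      state <- inf$state
      if (inf$leftover > 0) {
        fl$runoff_out["blue_i"] <- fl$runoff_out["blue_i"] + inf$leftover
        log_event(log_env, "blue_i", "runoff", inf$leftover)
      }
    }
  }
  # Ponded water infiltrates the puddled (root-zone) compartments until
  # they saturate; deeper layers only receive the slower drainage cascade.
  if (bund_height > 0 && sum(state$pond) > 0) {
    bounds <- cumsum(c(0, state$thicknesses))
    puddled <- which(bounds[-length(bounds)] < root_depth)
    room <- sum(state$sat_mm[puddled]) - sum(state$M[, puddled])
    take <- min(sum(state$pond), max(room, 0))
    if (take > 0) {
      ptot <- sum(state$pond)
      rem <- state$pond * (take / ptot)
      state$pond <- state$pond - rem
      left <- take
      for (i in puddled) {
        cap <- state$sat_mm[i] - sum(state$M[, i])
        put <- min(cap, left)
        if (put > 0) {
          state$M[, i] <- state$M[, i] + rem * (put / take)
          log_event(log_env, "pond", paste0("c", i), put)
          left <- left - put
        }
        if (left <= 0) break
      }
    }
  }

  # Any ponding still above the bund after infiltration spills as runoff
  if (bund_height > 0) {
    spill <- sum(state$pond) - bund_height
    if (spill > 0) {
      ptot <- sum(state$pond)
      rem <- state$pond * (spill / ptot)
      state$pond <- state$pond - rem
      fl$runoff_out <- fl$runoff_out + rem
      log_event(log_env, "pond", "runoff", spill)
    }
  }

  # 4. Drainage cascade; puddled (bunded) rice soils drain far slower
  tau_eff <- if (bund_height > 0) 0.1 * state$hyd$tau else state$hyd$tau
  dr_out <- drain_logged(state, log_env, tau = tau_eff)
  state <- dr_out$state
  fl$deep_percolation_out <- dr_out$percolation

  # 5. Evaporation and transpiration
  rz <- root_zone_status(state, root_depth)
  ks <- water_stress_coefficients(rz$dr, max(rz$taw, 1e-9), p_up)
  e_pot <- 1.1 * (1 - canopy_cover) * et0 * fw_evap
  t_pot <- kcb * canopy_cover * et0 * ks$stomatal
  et <- extract_et_logged(state, e_pot, t_pot, rz$weights, log_env)
  state <- et$state
  fl$evaporation_out <- et$evaporation
  fl$transpiration_out <- et$transpiration

  out <- list(state = state, fluxes = fl, ks_stomatal = ks$stomatal,
              ks_expansion = ks$expansion)
  if (log) out$events <- log_env$events
  out
}

log_event <- function(log_env, from, to, amount) {
  if (is.null(log_env) || amount <= 0) return(invisible())
  log_env$events[[length(log_env$events) + 1L]] <-
    list(from = from, to = to, amount = amount)
  invisible()
}
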