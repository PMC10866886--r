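# Independent parcel-ledger oracle for the colour-traced water balance.
#
# Replays the event log of step_water_balance() with a completely different
# data structure: every inflow becomes an individual parcel tagged with its
# colour at creation; every transfer removes a proportional share of every
# parcel in the donor store and appends the shares as new parcels in the
# receiver; sinks accumulate per colour. The per-colour storage and sink
# totals must agree with the fractional implementation.

parcel_replay <- function(events, n_comp, initial = NULL) {
  sources <- c("green", "blue_i", "blue_cr")
  sinks <- c("runoff", "evap", "transp", "perc")
  stores <- c("pond", paste0("c", seq_len(n_comp)))
  # each store: parallel vectors of parcel colours and masses
  st <- setNames(lapply(stores, function(s) {
    list(colour = character(), mass = numeric())
  }), stores)
  add_parcels <- function(store, colours, masses) {
    keep <- masses > 1e-12  # negligible parcels are dropped
    out <- list(colour = c(store$colour, colours[keep]),
                mass = c(store$mass, masses[keep]))
    if (length(out$mass) > 4000) {
      # cap the ledger: merging parcels of equal colour is lossless for
      # the per-colour totals under proportional moves (linearity)
      agg <- tapply(out$mass, out$colour, sum)
      out <- list(colour = names(agg), mass = as.numeric(agg))
    }
    out
  }
  if (!is.null(initial)) {
    # pre-existing storage enters as day-zero parcels
    for (i in seq_len(ncol(initial))) {
      cl <- sources[initial[, i] > 0]
      st[[paste0("c", i)]] <- add_parcels(st[[paste0("c", i)]], cl,
                                          initial[initial[, i] > 0, i])
    }
  }
  sunk <- matrix(0, nrow = 3, ncol = length(sinks),
                 dimnames = list(sources, sinks))
  for (ev in events) {
    if (ev$from %in% sources) {
      if (ev$to %in% sinks) {
        # e.g. rain routed straight to runoff before infiltration
        sunk[ev$from, ev$to] <- sunk[ev$from, ev$to] + ev$amount
      } else {
        st[[ev$to]] <- add_parcels(st[[ev$to]], ev$from, ev$amount)
      }
    } else {
      donor <- st[[ev$from]]
      tot <- sum(donor$mass)
      stopifnot(tot + 1e-9 >= ev$amount)
      f <- min(ev$amount / tot, 1)
      moved_mass <- donor$mass * f
      st[[ev$from]]$mass <- donor$mass - moved_mass
      if (ev$to %in% sinks) {
        for (cl in sources) {
          sunk[cl, ev$to] <- sunk[cl, ev$to] +
            sum(moved_mass[donor$colour == cl])
        }
      } else {
        st[[ev$to]] <- add_parcels(st[[ev$to]], donor$colour, moved_mass)
      }
    }
  }
  storage <- sapply(stores, function(s) {
    sapply(sources, function(cl) sum(st[[s]]$mass[st[[s]]$colour == cl]))
  })
  list(storage = storage, sinks = sunk)
}

# Drive the daily step over a synthetic spell, keeping the event log and
# the per-day fluxes for cross-checks.
simulate_logged_days <- function(state, days, gw_depth = Inf,
                                 system = "rainfed", rice = FALSE) {
  events <- list()
  fluxes <- list()
  for (i in seq_len(nrow(days))) {
    d <- days[i, ]
    st <- step_water_balance(
      state, d$precip, d$et0, d$cc, d$kcb, d$root, irrigation = d$irr,
      water_table_depth = gw_depth, system = system, crop_is_rice = rice,
      log = TRUE
    )
    state <- st$state
    events <- c(events, st$events)
    fluxes[[i]] <- st$fluxes
  }
  list(state = state, events = events, fluxes = fluxes)
}
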