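#' Convert dry yield to fresh yield
#'
#' `fresh = dry / (1 - wc)` where `wc` is the crop's fresh-mass water
#' content fraction.
#'
#' @param dry_yield Dry yield, t/ha.
#' @param wc Water content fraction in \[0, 1).
#' @return Fresh yield, t/ha.
#' @export
dry_to_fresh <- function(dry_yield, wc) {
  if (any(wc < 0 | wc >= 1)) abort("water content fraction must lie in [0, 1)")
  dry_yield / (1 - wc)
}

#' Unit water footprint from crop water use and yield
#'
#' `uWF = 10 * CWU / yield` (mm converts to m3/ha via the factor 10), per
#' colour component. Zero yield leaves the value undefined (NA, cell
#' masked).
#'
#' @param cwu Crop water use component, mm.
#' @param yield Scaled fresh yield, t/ha.
#' @return Unit water footprint, m3/t.
#' @export
compute_uwf <- function(cwu, yield) {
  ifelse(yield > 0, 10 * cwu / yield, NA_real_)
}

#' Water footprint of production
#'
#' `pWF = uWF * production`, per colour component.
#'
#' @param uwf Unit water footprint, m3/t.
#' @param production Crop production, t.
#' @return Production water footprint, m3.
#' @export
compute_pwf <- function(uwf, production) {
  if (any(production < 0, na.rm = TRUE)) abort("production must be >= 0")
  uwf * production
}

#' Reported crop water use across multiple seasons
#'
#' Crops planted several times a year (such as rice) report the
#' area-weighted mean of the season CWU values, not the sum.
#'
#' @param cwu Per-season CWU values, mm.
#' @param areas Per-season harvested areas (weights).
#' @return Weighted mean CWU, mm.
#' @export
multi_season_cwu <- function(cwu, areas = rep(1, length(cwu))) {
  if (!length(cwu)) abort("at least one season required")
  weighted.mean(cwu, areas)
}

#' Synthesise a national census from the simulated truth
#'
#' National annual harvested area and production per crop, equal to the
#' simulation's own bookkeeping perturbed by a relative noise term drawn
#' from the census substream. `noise = 0` reproduces the truth exactly, so
#' all downstream scaling factors collapse to 1.
#'
#' @param truth Tibble with `country`, `crop`, `year`, `harvarea_ha`,
#'   `production_t` (the simulated truth).
#' @param noise Relative perturbation amplitude.
#' @param seed Root seed (census substream is derived from it).
#' @return A census tibble with the same columns.
#' @export
synthesize_census <- function(truth, noise, seed) {
  if (noise == 0) return(truth)
  with_substream(seed, "census", {
    truth %>%
      arrange(.data$country, .data$crop, .data$year) %>%
      mutate(
        harvarea_ha = .data$harvarea_ha * (1 + runif(n(), -noise, noise)),
        production_t = .data$production_t * (1 + runif(n(), -noise, noise))
      )
  })
}

#' Project reference-year areas and scale them to the census
#'
#' Fine-cell harvested areas at the reference year are projected through
#' per-country-crop trend indices, then uniformly rescaled per (country,
#' crop, year) — production systems summed — so national totals equal the
#' census harvested area exactly. The rainfed/irrigated split within each
#' cell is preserved (proportional rescale).
#'
#' @param areas Base-year fine areas: `crop`, `system`, `fine_cell`,
#'   `coarse_cell`, `country`, `area_ha`.
#' @param trends Tibble `country`, `crop`, `year`, `index`.
#' @param census Census tibble (see [synthesize_census()]); `NULL` skips
#'   the census rescale (projection only).
#' @return Per-year fine areas with an `area_scale` column.
#' @export
project_and_scale_areas <- function(areas, trends, census = NULL) {
  proj <- areas %>%
    inner_join(trends, by = c("country", "crop"),
               relationship = "many-to-many") %>%
    mutate(area_ha = .data$area_ha * .data$index) %>%
    select(-"index")
  if (is.null(census)) return(mutate(proj, area_scale = 1))
  nat <- proj %>%
    group_by(.data$country, .data$crop, .data$year) %>%
    summarise(projected_ha = sum(.data$area_ha), .groups = "drop") %>%
    left_join(census[, c("country", "crop", "year", "harvarea_ha")],
              by = c("country", "crop", "year")) %>%
    mutate(area_scale = dplyr::case_when(
      is.na(.data$harvarea_ha) ~ 1,
      .data$projected_ha > 0 ~ .data$harvarea_ha / .data$projected_ha,
      .data$harvarea_ha > 0 ~ NA_real_,  # unallocatable
      TRUE ~ 1
    ))
  proj %>%
    left_join(nat[, c("country", "crop", "year", "area_scale")],
              by = c("country", "crop", "year")) %>%
    mutate(area_ha = .data$area_ha * .data$area_scale)
}

#' National yield scaling factors
#'
#' `k = census production / simulated production` per (country, crop,
#' year); the factor is applied equally to every rainfed and irrigated
#' cell yield in the country (a factor of 0.5 halves all of them). Crop
#' water use is never scaled. Zero simulated production against a positive
#' census leaves the factor undefined (flagged NA).
#'
#' @param production Tibble `country`, `crop`, `year`, `production_t`
#'   (simulated, after area scaling).
#' @param census Census tibble with `production_t`.
#' @return Tibble `country`, `crop`, `year`, `yield_scale`.
#' @export
yield_scaling_factors <- function(production, census) {
  production %>%
    rename(sim_production_t = "production_t") %>%
    left_join(census[, c("country", "crop", "year", "production_t")],
              by = c("country", "crop", "year")) %>%
    mutate(yield_scale = dplyr::case_when(
      is.na(.data$production_t) ~ 1,
      .data$sim_production_t > 0 ~ .data$production_t / .data$sim_production_t,
      .data$production_t > 0 ~ NA_real_,
      TRUE ~ 1
    )) %>%
    select("country", "crop", "year", "yield_scale")
}

#' Apply national yield scaling factors to cell yields
#'
#' @param cell_yields Tibble with `country`, `crop`, `year` and a yield
#'   column named by `col`.
#' @param factors From [yield_scaling_factors()].
#' @param col Name of the yield column to scale.
#' @return `cell_yields` with the scaled column and `yield_scale` kept.
#' @export
apply_yield_scaling <- function(cell_yields, factors, col = "fresh_yield") {
  cell_yields %>%
    left_join(factors, by = c("country", "crop", "year")) %>%
    mutate(yield_scale = dplyr::coalesce(.data$yield_scale, 1),
           !!col := .data[[col]] * .data$yield_scale)
}

#' Post-process simulated seasons into water-footprint accounts
#'
#' The full accounting chain: multi-season averaging to one record per
#' (cell, crop, system, year); dry-to-fresh conversion; area projection
#' and census scaling; national yield scaling; unit water footprints
#' (green, blue from capillary rise, blue from irrigation); coarse-to-fine
#' allocation; production water footprints; and national records in the
#' published 13-column schema.
#'
#' @param world A `wf_world`.
#' @param seasons Output of [wf_simulate()].
#' @param census Optional census tibble; by default synthesised from the
#'   simulated truth with the configured `census_noise`.
#' @return A `wf_run` object (see [tidy.wf_run()], [glance.wf_run()]).
#' @export
wf_account <- function(world, seasons, census = NULL) {
  cfg <- world$config

  cell_year <- seasons %>%
    group_by(.data$cell, .data$crop, .data$system, year = .data$harvest_year) %>%
    summarise(
      cwu_green = multi_season_cwu(.data$cwu_green),
      cwu_blue_cr = multi_season_cwu(.data$cwu_blue_cr),
      cwu_blue_i = multi_season_cwu(.data$cwu_blue_i),
      dry_yield = mean(.data$dry_yield),
      irrigation_mm = mean(.data$irrigation_mm),
      .groups = "drop"
    ) %>%
    left_join(world$crops[, c("crop", "wc")], by = "crop") %>%
    mutate(fresh_yield = dry_to_fresh(.data$dry_yield, .data$wc)) %>%
    select(-"wc")

  # Projected (trend only) fine areas, for the truth bookkeeping
  proj <- project_and_scale_areas(world$areas, world$trends, census = NULL)

  fine_yield <- proj %>%
    inner_join(cell_year[, c("cell", "crop", "system", "year", "fresh_yield")],
               by = c("coarse_cell" = "cell", "crop", "system", "year"))

  truth <- fine_yield %>%
    group_by(.data$country, .data$crop, .data$year) %>%
    summarise(harvarea_ha = sum(.data$area_ha),
              production_t = sum(.data$fresh_yield * .data$area_ha),
              .groups = "drop")

  if (is.null(census)) {
    census <- synthesize_census(truth, cfg$census_noise, cfg$seed)
  }

  # Area scaling to the census, then simulated production on scaled areas
  areas_scaled <- project_and_scale_areas(world$areas, world$trends, census)
  sim_prod <- areas_scaled %>%
    inner_join(cell_year[, c("cell", "crop", "system", "year", "fresh_yield")],
               by = c("coarse_cell" = "cell", "crop", "system", "year")) %>%
    group_by(.data$country, .data$crop, .data$year) %>%
    summarise(production_t = sum(.data$fresh_yield * .data$area_ha),
              .groups = "drop")

  factors <- yield_scaling_factors(sim_prod, census)

  cell_scaled <- cell_year %>%
    left_join(dplyr::distinct(world$cells[, c("cell", "country")]), by = "cell") %>%
    apply_yield_scaling(factors, col = "fresh_yield") %>%
    mutate(
      uwf_green = compute_uwf(.data$cwu_green, .data$fresh_yield),
      uwf_blue_cr = compute_uwf(.data$cwu_blue_cr, .data$fresh_yield),
      uwf_blue_i = compute_uwf(.data$cwu_blue_i, .data$fresh_yield),
      uwf_total = .data$uwf_green + .data$uwf_blue_cr + .data$uwf_blue_i,
      cwu_total = .data$cwu_green + .data$cwu_blue_cr + .data$cwu_blue_i
    )

  # Coarse-to-fine allocation: intensive values copy to fine cells with
  # positive area; production and pWF are extensive.
  fine <- areas_scaled %>%
    filter(.data$area_ha > 0) %>%
    left_join(world$fine_cells[, c("fine_cell", "lat", "lon")],
              by = "fine_cell") %>%
    inner_join(cell_scaled,
               by = c("coarse_cell" = "cell", "crop", "system", "year",
                      "country")) %>%
    mutate(
      production_t = .data$fresh_yield * .data$area_ha,
      pwf_green = compute_pwf(.data$uwf_green, .data$production_t),
      pwf_blue_cr = compute_pwf(.data$uwf_blue_cr, .data$production_t),
      pwf_blue_i = compute_pwf(.data$uwf_blue_i, .data$production_t),
      pwf_blue = .data$pwf_blue_cr + .data$pwf_blue_i,
      pwf_total = .data$pwf_green + .data$pwf_blue
    )

  national <- national_records(fine)

  structure(list(
    world = world, seasons = seasons, cell_year = cell_scaled,
    areas = areas_scaled, truth = truth, census = census,
    yield_factors = factors, fine = fine, national = national
  ), class = "wf_run")
}

#' @export
print.wf_run <- function(x, ...) {
  cat("<wf_run> ", nrow(x$seasons), " seasons, ",
      nrow(x$national), " national records (",
      length(unique(x$national$country_code)), " countries x ",
      length(unique(x$national$crop_name)), " crops)\n", sep = "")
  invisible(x)
}

#' Run the whole pipeline from a config
#'
#' Convenience wrapper: [generate_world()], [wf_simulate()], [wf_account()].
#'
#' @param config A [world_config()].
#' @return A `wf_run`.
#' @export
wf_pipeline <- function(config = world_config()) {
  world <- generate_world(config)
  seasons <- wf_simulate(world)
  wf_account(world, seasons)
}
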