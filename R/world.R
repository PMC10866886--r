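#' Configuration for the synthetic miniature world
#'
#' Defines a reproducible toy world: a coarse simulation grid subdivided
#' into a finer allocation grid, contiguous countries, per-region climate,
#' a linear CO2 trend and the census perturbation level. Defaults give a
#' 4x4 coarse grid (fine factor 2), 3 countries and 12 simulated years —
#' the first two are the warm-up, so ten years are reported.
#'
#' @param seed Root seed; all randomness flows from it via named substreams.
#' @param years Number of simulated calendar years (>= 3; the first two are
#'   warm-up).
#' @param start_year First simulated calendar year.
#' @param coarse_rows,coarse_cols Simulation grid dimensions.
#' @param fine_factor Integer subdivision of each coarse cell per axis
#'   (allocation grid resolution).
#' @param n_countries Number of countries (contiguous column blocks).
#' @param climate_params Optional tibble with one row per country:
#'   `annual_precip_mm`, `wet_day_prob`, `temp_mean`, `temp_amplitude`,
#'   `wind_mean`, `rh_mean`.
#' @param co2_start,co2_trend CO2 at `start_year` (ppm) and trend (ppm/yr).
#' @param census_noise Relative perturbation of the census against the
#'   simulated truth (0 gives exact self-consistency).
#' @return A `wf_world_config` list.
#' @export
world_config <- function(seed = 42, years = 12, start_year = 2008,
                         coarse_rows = 4, coarse_cols = 4, fine_factor = 2,
                         n_countries = 3, climate_params = NULL,
                         co2_start = 370, co2_trend = 2,
                         census_noise = 0.05) {
  if (years < 3) abort("years must be >= 3 (two warm-up years plus one reported)")
  if (fine_factor < 1) abort("fine_factor must be >= 1")
  if (n_countries > coarse_rows * coarse_cols) {
    abort("n_countries exceeds the number of coarse cells")
  }
  if (is.null(climate_params)) {
    climate_params <- tibble(
      country = seq_len(n_countries),
      annual_precip_mm = rep_len(c(1200, 800, 500, 950, 650), n_countries),
      wet_day_prob = rep_len(c(0.45, 0.35, 0.25, 0.40, 0.30), n_countries),
      temp_mean = rep_len(c(13, 15, 17, 14, 16), n_countries),
      temp_amplitude = rep_len(c(8, 10, 12, 9, 11), n_countries),
      wind_mean = rep_len(c(2.0, 2.5, 3.0, 2.2, 2.8), n_countries),
      rh_mean = rep_len(c(75, 70, 60, 72, 65), n_countries)
    )
  }
  structure(list(
    seed = seed, years = years, start_year = start_year,
    coarse_rows = coarse_rows, coarse_cols = coarse_cols,
    fine_factor = fine_factor, n_countries = n_countries,
    climate_params = climate_params,
    co2_start = co2_start, co2_trend = co2_trend, co2_ref = 369.41,
    census_noise = census_noise,
    warmup_years = 2,
    lat0 = 40, lon0 = 0, cellsize = 1
  ), class = "wf_world_config")
}

# Coarse-cell layout: id, row, col, centre coordinates, country.
world_cells <- function(config) {
  grid <- tidyr::expand_grid(row = seq_len(config$coarse_rows),
                             col = seq_len(config$coarse_cols))
  country_of_col <- as.integer(cut(grid$col, breaks = config$n_countries,
                                   labels = FALSE))
  grid %>%
    mutate(
      cell = dplyr::row_number(),
      lat = config$lat0 + (.data$row - 0.5) * config$cellsize,
      lon = config$lon0 + (.data$col - 0.5) * config$cellsize,
      country = country_of_col
    ) %>%
    select("cell", "row", "col", "lat", "lon", "country")
}

#' Generate daily weather for one coarse cell
#'
#' A stochastic daily weather generator: wet-day occurrence follows a
#' first-order two-state chain; wet-day amounts are gamma distributed;
#' temperature is a sinusoidal annual cycle plus AR(1) noise; shortwave
#' radiation is a clear-sky fraction of extraterrestrial radiation,
#' reduced on wet days; wind is gamma and relative humidity rises on wet
#' days. Years are 365 days (no leap days). Fully deterministic given the
#' root seed and the cell id.
#'
#' @param config A [world_config()].
#' @param cell Coarse-cell id.
#' @param noise If `FALSE`, produce the deterministic mean climate
#'   (noise-free sinusoidal temperatures, uniform drizzle) — used for
#'   heat-unit calibration checks.
#' @param years Number of years to generate (default from config).
#' @return A tibble with columns `year`, `doy`, `precip`, `tmin`, `tmax`,
#'   `srad`, `wind`, `rh`.
#' @export
generate_weather <- function(config, cell, noise = TRUE, years = config$years) {
  cells <- world_cells(config)
  if (!cell %in% cells$cell) abort("unknown coarse cell")
  info <- cells[cells$cell == cell, ]
  cp <- config$climate_params[info$country, ]
  ndays <- years * 365L
  doy <- rep(seq_len(365L), years)
  year <- rep(config$start_year + seq_len(years) - 1L, each = 365L)

  tcycle <- cp$temp_mean + cp$temp_amplitude * cos(2 * pi * (doy - 200) / 365)
  ra <- extraterrestrial_radiation(info$lat, doy)

  if (!noise) {
    # Mean climate: drizzle spread evenly, sinusoidal temperature.
    precip <- rep(cp$annual_precip_mm / 365, ndays)
    dtr <- 8
    return(tibble(year = year, doy = doy, precip = precip,
                  tmin = tcycle - dtr / 2, tmax = tcycle + dtr / 2,
                  srad = pmax(0.55 * ra, 0.5), wind = cp$wind_mean,
                  rh = cp$rh_mean))
  }

  with_substream(config$seed, paste0("weather/", cell), {
    pw <- cp$wet_day_prob
    p11 <- min(0.9, pw + 0.25)
    p01 <- if (pw < 1) pw * (1 - p11) / (1 - pw) else 1
    u <- runif(ndays)
    wet <- logical(ndays)
    prev <- runif(1) < pw
    for (i in seq_len(ndays)) {
      p <- if (prev) p11 else p01
      wet[i] <- u[i] < p
      prev <- wet[i]
    }
    shape <- 0.75
    mean_amt <- cp$annual_precip_mm / (365 * pw)
    precip <- numeric(ndays)
    nwet <- sum(wet)
    if (nwet > 0 && pw > 0) {
      precip[wet] <- rgamma(nwet, shape = shape, scale = mean_amt / shape)
    }
    ar <- as.numeric(stats::filter(rnorm(ndays, 0, 2 * sqrt(1 - 0.7^2)),
                                   0.7, method = "recursive"))
    tmean <- tcycle + ar
    dtr <- ifelse(wet, 6, 10)
    kt <- pmin(pmax(ifelse(wet, 0.35, 0.70) + rnorm(ndays, 0, 0.05), 0.10), 0.75)
    wind <- rgamma(ndays, shape = 4, scale = cp$wind_mean / 4)
    rh <- pmin(pmax(cp$rh_mean + ifelse(wet, 10, 0) + rnorm(ndays, 0, 5), 20), 98)
    tibble(year = year, doy = doy, precip = precip,
           tmin = tmean - dtr / 2, tmax = tmean + dtr / 2,
           srad = pmax(kt * ra, 0.3), wind = wind, rh = rh)
  })
}

#' Generate the synthetic world
#'
#' Builds the full static input stack for the pipeline: coarse cells with
#' soils, elevation and country labels; the fine allocation grid; a
#' monthly groundwater-depth climatology (some cells shallow, some deep);
#' the crop archetype set with calendars and irrigation policies; per-crop
#' rainfed/irrigated harvested-area maps on the fine grid (reference
#' year); per-country-crop area trend indices; the annual CO2 series; and
#' daily weather with ET0 for every coarse cell. The national census is
#' synthesised later from the simulated truth (see [synthesize_census()]),
#' so that a zero `census_noise` yields exact self-consistency.
#'
#' @param config A [world_config()].
#' @return A `wf_world` list.
#' @export
generate_world <- function(config) {
  cells <- world_cells(config)
  ncell <- nrow(cells)

  with_substream(config$seed, "soils", {
    cells$elevation <- round(runif(ncell, 50, 300))
    cells$texture <- sample(c("loam", "sandy_loam", "clay_loam"), ncell,
                            replace = TRUE)
  })

  # Monthly groundwater climatology; force at least one shallow (< 2 m)
  # and one deep (> 4 m) cell.
  gw_base <- with_substream(config$seed, "groundwater", runif(ncell, 0.8, 6))
  if (!any(gw_base < 2)) gw_base[1] <- 1.2
  if (!any(gw_base > 4)) gw_base[2] <- 5.0
  gw <- tidyr::expand_grid(cell = cells$cell, month = 1:12) %>%
    mutate(depth_m = pmax(0, gw_base[.data$cell] +
                            0.4 * sin(2 * pi * (.data$month - 3) / 12)))

  # Fine allocation grid
  f <- config$fine_factor
  fine <- tidyr::expand_grid(cell = cells$cell,
                             fr = seq_len(f), fc = seq_len(f)) %>%
    left_join(cells, by = "cell") %>%
    mutate(
      fine_cell = dplyr::row_number(),
      lat = config$lat0 + (.data$row - 1) * config$cellsize +
        (.data$fr - 0.5) * config$cellsize / f,
      lon = config$lon0 + (.data$col - 1) * config$cellsize +
        (.data$fc - 0.5) * config$cellsize / f
    ) %>%
    select("fine_cell", coarse_cell = "cell", "lat", "lon", "country")

  crops <- crop_parameters()
  policies <- irrigation_policies()

  # Crop assignment: each coarse cell hosts 2-3 archetypes, chosen by a
  # deterministic rotation so all five habits appear across the world.
  ncrop <- nrow(crops)
  assign_tbl <- purrr::map_dfr(cells$cell, function(cl) {
    k <- 2 + (cl %% 2)
    idx <- ((cl - 1 + seq_len(k) - 1) %% ncrop) + 1
    tibble(cell = cl, crop = crops$crop[idx])
  })

  areas <- with_substream(config$seed, "areas", {
    purrr::map_dfr(seq_len(nrow(assign_tbl)), function(i) {
      cl <- assign_tbl$cell[i]
      cr <- assign_tbl$crop[i]
      total <- runif(1, 500, 3000)
      irr_share <- runif(1, 0.15, 0.60)
      sub <- fine[fine$coarse_cell == cl, ]
      purrr::map_dfr(c("rainfed", "irrigated"), function(sys) {
        w <- rgamma(nrow(sub), shape = 1.5, scale = 1)
        w <- w / sum(w)
        amt <- total * ifelse(sys == "irrigated", irr_share, 1 - irr_share)
        tibble(crop = cr, system = sys, fine_cell = sub$fine_cell,
               coarse_cell = cl, country = sub$country,
               area_ha = amt * w)
      })
    })
  })

  report_years <- (config$start_year + config$warmup_years):
    (config$start_year + config$years - 1)
  base_year <- report_years[1]
  trends <- with_substream(config$seed, "trends", {
    tidyr::expand_grid(country = seq_len(config$n_countries),
                       crop = crops$crop) %>%
      mutate(growth = runif(n(), -0.01, 0.02)) %>%
      tidyr::expand_grid(year = report_years) %>%
      mutate(index = (1 + .data$growth)^(.data$year - base_year)) %>%
      select("country", "crop", "year", "index")
  })

  co2 <- tibble(
    year = config$start_year + seq_len(config$years) - 1,
    ppm = config$co2_start +
      config$co2_trend * (seq_len(config$years) - 1)
  )

  weather <- purrr::map(cells$cell, function(cl) {
    w <- generate_weather(config, cl)
    info <- cells[cells$cell == cl, ]
    reference_et0(w, latitude = info$lat, elevation = info$elevation)
  })
  names(weather) <- as.character(cells$cell)

  structure(list(
    config = config, cells = cells, fine_cells = fine, groundwater = gw,
    crops = crops, policies = policies, areas = areas, trends = trends,
    co2 = co2, weather = weather,
    report_years = report_years, base_year = base_year
  ), class = "wf_world")
}

#' @export
print.wf_world <- function(x, ...) {
  cat("<wf_world> ", nrow(x$cells), " coarse cells (fine factor ",
      x$config$fine_factor, "), ", x$config$n_countries, " countries, ",
      nrow(x$crops), " crops, years ", min(x$report_years), "-",
      max(x$report_years), " (+", x$config$warmup_years, " warm-up)\n",
      sep = "")
  invisible(x)
}

#' Daily groundwater depth from the monthly climatology
#'
#' Linearly interpolates the 12-value monthly climatology (anchored at
#' mid-month) to a daily series for the requested number of years.
#'
#' @param gw_monthly Tibble with `month` and `depth_m` for one cell.
#' @param years Number of years.
#' @return Numeric vector of daily depths (m), length `years * 365`.
#' @export
daily_groundwater_depth <- function(gw_monthly, years) {
  mids <- cumsum(c(0, rep(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30), 1)))[1:12] + 15
  x <- c(mids[12] - 365, mids, mids[1] + 365)
  y <- gw_monthly$depth_m[c(12, 1:12, 1)]
  one <- approx(x, y, xout = seq_len(365))$y
  rep(one, years)
}
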