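# The published national CSV schema, in exact column order.
WF_NATIONAL_SCHEMA <- c(
  "crop_code", "crop_name", "country_code", "country_name", "year",
  "harvarea_ha", "irrigated_harvarea_fraction", "production_t",
  "crop_yield_t_ha", "wfg_m3_t", "wfb_cr_m3_t", "wfb_i_m3_t", "wf_tot_m3_t"
)

#' Allocate a coarse-cell value to fine cells
#'
#' Intensive quantities (uWF, CWU, yield) are copied unchanged to every
#' fine cell with positive harvested area; extensive quantities (pWF,
#' production) are distributed proportionally to area so totals are
#' conserved. Fine cells without area receive `NA`.
#'
#' @param value The coarse-cell value.
#' @param fine_areas Harvested areas of the fine cells within the coarse
#'   cell (>= 0).
#' @param kind `"intensive"` or `"extensive"`.
#' @return Numeric vector of fine-cell values.
#' @export
allocate_coarse_to_fine <- function(value, fine_areas,
                                    kind = c("intensive", "extensive")) {
  kind <- match.arg(kind)
  if (any(fine_areas < 0)) abort("fine areas must be >= 0")
  tot <- sum(fine_areas)
  if (tot == 0) {
    if (!is.na(value) && value != 0) {
      abort("nonzero coarse value with no fine area to receive it",
            class = "wf_unallocatable")
    }
    return(rep(NA_real_, length(fine_areas)))
  }
  if (kind == "intensive") {
    ifelse(fine_areas > 0, value, NA_real_)
  } else {
    value * fine_areas / tot
  }
}

#' Weighted national aggregate
#'
#' `sum(v w) / sum(w)`. Unit water footprints aggregate with production
#' weights; crop water use and yields with harvested-area weights.
#'
#' @param values Cell values.
#' @param weights Non-negative weights (production or area).
#' @return The weighted mean, or `NA` if all weights are zero.
#' @export
national_aggregate <- function(values, weights) {
  if (any(weights < 0)) abort("weights must be >= 0")
  keep <- !is.na(values) & weights > 0
  if (!any(keep)) return(NA_real_)
  weighted.mean(values[keep], weights[keep])
}

#' Weighted decade average
#'
#' Weighted mean over a multi-year window (production weights for unit
#' water footprints, harvested-area weights for crop water use), damping
#' the contribution of years with extreme values.
#'
#' @param values Annual values.
#' @param weights Annual weights.
#' @return Weighted mean.
#' @export
decade_average <- function(values, weights = rep(1, length(values))) {
  if (!length(values)) abort("at least one year required")
  national_aggregate(values, weights)
}

# National records in the published 13-column schema, from the fine table.
national_records <- function(fine) {
  crops <- sort(unique(fine$crop))
  fine %>%
    group_by(.data$country, .data$crop, .data$year) %>%
    summarise(
      harvarea_ha = sum(.data$area_ha),
      irrigated_harvarea_fraction =
        sum(.data$area_ha[.data$system == "irrigated"]) / sum(.data$area_ha),
      wfg_m3_t = national_aggregate(.data$uwf_green, .data$production_t),
      wfb_cr_m3_t = national_aggregate(.data$uwf_blue_cr, .data$production_t),
      wfb_i_m3_t = national_aggregate(.data$uwf_blue_i, .data$production_t),
      production_t = sum(.data$production_t),
      crop_yield_t_ha = sum(.data$production_t) / sum(.data$area_ha),
      .groups = "drop"
    ) %>%
    mutate(
      wf_tot_m3_t = .data$wfg_m3_t + .data$wfb_cr_m3_t + .data$wfb_i_m3_t,
      crop_code = match(.data$crop, crops),
      crop_name = .data$crop,
      country_code = .data$country,
      country_name = sprintf("Country_%02d", .data$country)
    ) %>%
    select(all_of(WF_NATIONAL_SCHEMA))
}

#' Write the national records CSV
#'
#' Writes the 13-column national dataset with exactly the published header
#' names and order; refuses any other schema.
#'
#' @param national The `national` table of a `wf_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_national_csv <- function(national, path) {
  if (!identical(names(national), WF_NATIONAL_SCHEMA)) {
    abort("national table does not match the published 13-column schema")
  }
  readr::write_csv(national, path, progress = FALSE)
  invisible(path)
}

#' Decade-averaged gridded unit water footprints of one crop
#'
#' Seven layers per fine cell, production-weighted over the averaging
#' window: `wf_unit_rainfed`, `wf_unit_rainfed_blue`,
#' `wf_unit_rainfed_green`, `wf_unit_irrigated`, `wf_unit_irrigated_blue`,
#' `wf_unit_irrigated_green`, `wf_unit_total` (the total layer weights the
#' rainfed and irrigated layers by their average production).
#'
#' @param run A `wf_run`.
#' @param crop Crop name.
#' @param years Averaging window (default: the run's reported years).
#' @return Tibble: `fine_cell`, `lat`, `lon`, one column per layer.
#' @export
grid_uwf <- function(run, crop, years = run$world$report_years) {
  f <- run$fine %>% filter(.data$crop == !!crop, .data$year %in% years)
  by_sys <- f %>%
    group_by(.data$fine_cell, .data$lat, .data$lon, .data$system) %>%
    summarise(
      green = decade_average(.data$uwf_green, .data$production_t),
      blue = decade_average(.data$uwf_blue_cr + .data$uwf_blue_i,
                            .data$production_t),
      production = mean(.data$production_t),
      .groups = "drop"
    ) %>%
    mutate(sum_wf = .data$green + .data$blue)
  wide <- by_sys %>%
    tidyr::pivot_wider(id_cols = c("fine_cell", "lat", "lon"),
                       names_from = "system",
                       values_from = c("green", "blue", "sum_wf", "production"))
  for (cc in c("green_rainfed", "blue_rainfed", "sum_wf_rainfed",
               "production_rainfed", "green_irrigated", "blue_irrigated",
               "sum_wf_irrigated", "production_irrigated")) {
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  }
  wide %>%
    mutate(
      wf_unit_rainfed = .data$sum_wf_rainfed,
      wf_unit_rainfed_blue = .data$blue_rainfed,
      wf_unit_rainfed_green = .data$green_rainfed,
      wf_unit_irrigated = .data$sum_wf_irrigated,
      wf_unit_irrigated_blue = .data$blue_irrigated,
      wf_unit_irrigated_green = .data$green_irrigated,
      wf_unit_total = purrr::pmap_dbl(
        list(.data$sum_wf_rainfed, .data$sum_wf_irrigated,
             .data$production_rainfed, .data$production_irrigated),
        function(r, i, pr, pi) {
          national_aggregate(c(r, i), c(ifelse(is.na(pr), 0, pr),
                                        ifelse(is.na(pi), 0, pi)))
        })
    ) %>%
    select("fine_cell", "lat", "lon", dplyr::starts_with("wf_unit_"))
}

#' Decade-averaged gridded crop water use of one crop
#'
#' Three layers per fine cell, harvested-area weighted: `cwu_rainfed`,
#' `cwu_irrigated`, and `cwu_total` (area-weighted mean of the two).
#'
#' @inheritParams grid_uwf
#' @return Tibble: `fine_cell`, `lat`, `lon`, `cwu_rainfed`,
#'   `cwu_irrigated`, `cwu_total`.
#' @export
grid_cwu <- function(run, crop, years = run$world$report_years) {
  f <- run$fine %>% filter(.data$crop == !!crop, .data$year %in% years)
  by_sys <- f %>%
    group_by(.data$fine_cell, .data$lat, .data$lon, .data$system) %>%
    summarise(
      cwu = decade_average(.data$cwu_total, .data$area_ha),
      area = mean(.data$area_ha),
      .groups = "drop"
    )
  wide <- by_sys %>%
    tidyr::pivot_wider(id_cols = c("fine_cell", "lat", "lon"),
                       names_from = "system", values_from = c("cwu", "area"))
  for (cc in c("cwu_rainfed", "cwu_irrigated", "area_rainfed", "area_irrigated")) {
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  }
  wide %>%
    mutate(cwu_total = purrr::pmap_dbl(
      list(.data$cwu_rainfed, .data$cwu_irrigated,
           .data$area_rainfed, .data$area_irrigated),
      function(r, i, ar, ai) {
        national_aggregate(c(r, i), c(ifelse(is.na(ar), 0, ar),
                                      ifelse(is.na(ai), 0, ai)))
      })) %>%
    select("fine_cell", "lat", "lon", "cwu_rainfed", "cwu_irrigated",
           "cwu_total")
}

#' Annual gridded water footprints of production, all crops aggregated
#'
#' Five layer types per fine cell and year: `rainfed_green`,
#' `rainfed_blue`, `irrigated_green`, `irrigated_blue` and `total`
#' (m3/yr, summed over crops).
#'
#' @param run A `wf_run`.
#' @return Tibble: `fine_cell`, `lat`, `lon`, `year`, `wf_type`, `pwf_m3`.
#' @export
grid_pwf <- function(run) {
  base <- run$fine %>%
    group_by(.data$fine_cell, .data$lat, .data$lon, .data$year, .data$system) %>%
    summarise(green = sum(.data$pwf_green), blue = sum(.data$pwf_blue),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("green", "blue"), names_to = "colour",
                        values_to = "pwf_m3") %>%
    mutate(wf_type = paste0(.data$system, "_", .data$colour)) %>%
    select("fine_cell", "lat", "lon", "year", "wf_type", "pwf_m3")
  total <- base %>%
    group_by(.data$fine_cell, .data$lat, .data$lon, .data$year) %>%
    summarise(pwf_m3 = sum(.data$pwf_m3), .groups = "drop") %>%
    mutate(wf_type = "total")
  bind_rows(base, total)
}

# ---- NetCDF writers -------------------------------------------------------

# Turn a fine-cell tibble into a lon x lat matrix on the regular grid.
grid_matrix <- function(tbl, value_col, lons, lats) {
  m <- matrix(NA_real_, nrow = length(lons), ncol = length(lats))
  i <- match(round(tbl$lon, 9), round(lons, 9))
  j <- match(round(tbl$lat, 9), round(lats, 9))
  m[cbind(i, j)] <- tbl[[value_col]]
  m
}

#' Write gridded layers to NetCDF
#'
#' Writes one variable per layer column on a WGS84 lat/lon grid, with a
#' fill value (never 0) for masked cells. The geometry follows the data by
#' default; any regular grid, including the published 5-arcminute
#' 4320x2160 geometry ([global_5arcmin_geometry()]), can be passed
#' explicitly.
#'
#' @param tbl Tibble with `lat`, `lon` and the layer columns.
#' @param path Output file.
#' @param layers Character vector of layer column names.
#' @param units Units attribute for the variables.
#' @param geometry Optional `list(lon=, lat=)` grid-centre vectors.
#' @return `path`, invisibly.
#' @export
write_gridded_nc <- function(tbl, path, layers, units = "",
                             geometry = NULL) {
  if (!all(layers %in% names(tbl))) abort("missing layer columns")
  if (is.null(geometry)) {
    geometry <- list(lon = sort(unique(tbl$lon)), lat = sort(unique(tbl$lat)))
  }
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", geometry$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", geometry$lat)
  fill <- 1.0e20
  vars <- lapply(layers, function(nm) {
    ncdf4::ncvar_def(nm, units, list(dlon, dlat), missval = fill,
                     prec = "double")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(layers)) {
    ncdf4::ncvar_put(nc, vars[[k]],
                     grid_matrix(tbl, layers[k], geometry$lon, geometry$lat))
  }
  invisible(path)
}

#' Read gridded layers back from NetCDF
#'
#' @param path NetCDF file written by [write_gridded_nc()].
#' @return `list(lon, lat, layers)` with `layers` a named list of
#'   lon x lat matrices (fill values as `NA`).
#' @export
read_gridded_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  layers <- lapply(names(nc$var), function(nm) {
    m <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    matrix(as.numeric(m), nrow = length(lon))
  })
  names(layers) <- names(nc$var)
  list(lon = lon, lat = lat, layers = layers)
}

#' The published global 5-arcminute grid geometry
#'
#' Cell-centre coordinates of the 4320 x 2160 WGS84 grid
#' (0.083333 degree resolution, 180W-180E, 90S-90N).
#'
#' @return `list(lon, lat)`.
#' @export
global_5arcmin_geometry <- function() {
  res <- 1 / 12
  list(lon = seq(-180 + res / 2, 180 - res / 2, by = res),
       lat = seq(-90 + res / 2, 90 - res / 2, by = res))
}

#' Write the per-crop unit-water-footprint NetCDF
#'
#' Layers named exactly `wf_unit_{wf_type}` with types rainfed,
#' rainfed_blue, rainfed_green, irrigated, irrigated_blue,
#' irrigated_green, total.
#'
#' @param run A `wf_run`.
#' @param crop Crop name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wf_unit_nc <- function(run, crop, path) {
  g <- grid_uwf(run, crop)
  layers <- c("wf_unit_rainfed", "wf_unit_rainfed_blue",
              "wf_unit_rainfed_green", "wf_unit_irrigated",
              "wf_unit_irrigated_blue", "wf_unit_irrigated_green",
              "wf_unit_total")
  write_gridded_nc(g, path, layers, units = "m3 t-1 yr-1")
}

#' Write the per-crop crop-water-use NetCDF
#'
#' Layers named exactly `cwu_{cwu_type}` with types rainfed, irrigated,
#' total.
#'
#' @inheritParams write_wf_unit_nc
#' @return `path`, invisibly.
#' @export
write_cwu_nc <- function(run, crop, path) {
  g <- grid_cwu(run, crop)
  write_gridded_nc(g, path, c("cwu_rainfed", "cwu_irrigated", "cwu_total"),
                   units = "mm yr-1")
}

#' Write the production water-footprint NetCDFs
#'
#' One file per wf_type (`irrigated_blue`, `irrigated_green`,
#' `rainfed_blue`, `rainfed_green`, `total`), each holding one annual band
#' per reported year, named
#' `wf_prod_{wf_type}_{first}_{last}.nc`.
#'
#' @param run A `wf_run`.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_wf_prod_nc <- function(run, dir) {
  g <- grid_pwf(run)
  years <- sort(unique(g$year))
  lons <- sort(unique(run$fine$lon)); lats <- sort(unique(run$fine$lat))
  paths <- character(0)
  for (ty in c("irrigated_blue", "irrigated_green", "rainfed_blue",
               "rainfed_green", "total")) {
    path <- file.path(dir, sprintf("wf_prod_%s_%d_%d.nc", ty,
                                   min(years), max(years)))
    dlon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
    dlat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
    dt <- ncdf4::ncdim_def("time", "year", years)
    v <- ncdf4::ncvar_def(paste0("wf_prod_", ty), "m3 yr-1",
                          list(dlon, dlat, dt), missval = 1.0e20,
                          prec = "double")
    nc <- ncdf4::nc_create(path, list(v))
    arr <- array(NA_real_, dim = c(length(lons), length(lats), length(years)))
    sub_ty <- g[g$wf_type == ty, ]
    for (k in seq_along(years)) {
      arr[, , k] <- grid_matrix(sub_ty[sub_ty$year == years[k], ],
                                "pwf_m3", lons, lats)
    }
    ncdf4::ncvar_put(nc, v, arr)
    ncdf4::nc_close(nc)
    paths <- c(paths, path)
  }
  invisible(paths)
}
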