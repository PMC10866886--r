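#' Tidy a water-footprint run
#'
#' One row per (country, crop, year) in the published national schema.
#'
#' @param x A `wf_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wf_run
#' @export
tidy.wf_run <- function(x, ...) {
  as_tibble(x$national)
}

#' One-row summary of a water-footprint run
#'
#' @param x A `wf_run`.
#' @param ... Unused.
#' @return A one-row tibble: problem sizes, total green/blue production
#'   water footprints (m3) and the green share (%).
#' @method glance wf_run
#' @export
glance.wf_run <- function(x, ...) {
  pg <- sum(x$fine$pwf_green); pb <- sum(x$fine$pwf_blue)
  tibble(
    n_cells = nrow(x$world$cells),
    n_countries = x$world$config$n_countries,
    n_crops = nrow(x$world$crops),
    n_years = length(x$world$report_years),
    n_seasons = nrow(x$seasons),
    pwf_green_m3 = pg,
    pwf_blue_m3 = pb,
    green_share_pct = 100 * pg / (pg + pb),
    mean_yield_scale = mean(x$yield_factors$yield_scale, na.rm = TRUE)
  )
}

#' Plot national unit water footprints over time
#'
#' @param object A `wf_run`.
#' @param ... Unused.
#' @return A ggplot: total uWF by country and crop over the reported
#'   years, coloured by component.
#' @method autoplot wf_run
#' @export
autoplot.wf_run <- function(object, ...) {
  d <- object$national %>%
    tidyr::pivot_longer(c("wfg_m3_t", "wfb_cr_m3_t", "wfb_i_m3_t"),
                        names_to = "component", values_to = "uwf") %>%
    mutate(component = dplyr::recode(.data$component,
                                     wfg_m3_t = "green",
                                     wfb_cr_m3_t = "blue (capillary rise)",
                                     wfb_i_m3_t = "blue (irrigation)"))
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$uwf,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$country_name ~ .data$crop_name,
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression("unit water footprint (" *
                                             m^3 ~ t^-1 * ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map a gridded unit-water-footprint layer
#'
#' @param run A `wf_run`.
#' @param crop Crop name.
#' @param layer Layer name (one of the `wf_unit_*` layers).
#' @return A ggplot tile map on the fine grid.
#' @export
plot_uwf_map <- function(run, crop, layer = "wf_unit_total") {
  g <- grid_uwf(run, crop)
  ggplot2::ggplot(g, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data[[layer]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = paste(crop, layer), x = NULL, y = NULL,
                  fill = expression(m^3 ~ t^-1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
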