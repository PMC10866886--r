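#' Irrigation policy table
#'
#' The shipped per-crop irrigation policy: method (surface, sprinkler or
#' drip), the soil-moisture depletion fraction that triggers an
#' application (0.50 for the least water-stress-sensitive crops down to
#' 0.25 for the most sensitive), the rice flooding flag with its 300 mm
#' bund, and the wetted-surface fraction used to scale soil evaporation
#' (drip wets only part of the surface).
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A tibble with columns `crop`, `method`, `trigger_depletion`,
#'   `rice_flooding`, `bund_height_mm`, `wetted_fraction`.
#' @export
irrigation_policies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "irrigation_policies.csv", package = "wfcrop")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Daily irrigation decision
#'
#' Non-rice crops: when root-zone depletion exceeds the crop's trigger
#' fraction of total available water, apply exactly the depletion (refill
#' the root zone to field capacity), otherwise nothing. Flooded rice has no
#' threshold: the field is kept ponded by topping the pond up to its target
#' depth plus the saturation deficit of the root-zone compartments. Water
#' availability is never a constraint (applications reflect potential net
#' irrigation at field level).
#'
#' @param dr Root-zone depletion, mm.
#' @param taw Total available water in the root zone, mm.
#' @param trigger Trigger depletion fraction (ignored for rice).
#' @param rice Logical: flooded-rice rule.
#' @param state Soil state (required for rice).
#' @param root_depth Rooting depth, m (required for rice).
#' @param pond_target Target ponded depth for rice, mm.
#' @return Application depth, mm (colour blue_i).
#' @export
irrigation_decision <- function(dr, taw, trigger, rice = FALSE,
                                state = NULL, root_depth = NULL,
                                pond_target = 50) {
  if (rice) {
    stopifnot(!is.null(state), !is.null(root_depth))
    bounds <- cumsum(c(0, state$thicknesses))
    over <- pmax(pmin(bounds[-1], root_depth) - bounds[-length(bounds)], 0)
    frac <- over / state$thicknesses
    sat_def <- sum(frac * pmax(state$sat_mm - colSums(state$M), 0))
    return(max(0, pond_target - sum(state$pond)) + sat_def)
  }
  if (is.na(trigger)) abort("non-rice irrigation requires a trigger fraction")
  if (trigger < 0.25 - 1e-9 || trigger > 0.50 + 1e-9) {
    abort("trigger depletion must lie in [0.25, 0.50]")
  }
  if (dr > trigger * taw) dr else 0
}
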