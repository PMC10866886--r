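#' Reference evapotranspiration (FAO-56 Penman-Monteith)
#'
#' Computes daily reference evapotranspiration ET0 (mm/day) for a short
#' reference grass surface from daily weather, using the FAO-56
#' Penman-Monteith equation:
#'
#' \deqn{ET_0 = \frac{0.408\,\Delta (R_n - G) + \gamma \frac{900}{T+273}
#'   u_2 (e_s - e_a)}{\Delta + \gamma (1 + 0.34\, u_2)}}
#'
#' with the soil heat flux G = 0 at the daily time step, net radiation
#' derived from measured shortwave radiation (albedo 0.23) and a standard
#' longwave term, and the result clamped at zero.
#'
#' @param weather A data frame with one row per day and columns `tmax`,
#'   `tmin` (deg C), `rh` (relative humidity, %), `wind` (m/s at 2 m),
#'   `srad` (incoming shortwave, MJ m-2 day-1) and `doy` (day of year).
#' @param latitude Latitude in decimal degrees.
#' @param elevation Elevation above sea level, m.
#' @param net_radiation Optional net radiation (MJ m-2 day-1), bypassing the
#'   internal radiation balance (useful when Rn is known independently).
#' @return The input tibble with an `et0` column (mm/day), or a numeric
#'   vector if `weather` has a single row and `.vector = TRUE` internally.
#' @export
#' @examples
#' w <- tibble::tibble(tmax = 25, tmin = 12, rh = 60, wind = 2,
#'                     srad = 22, doy = 180)
#' reference_et0(w, latitude = 42, elevation = 100)
reference_et0 <- function(weather, latitude, elevation = 0, net_radiation = NULL) {
  stopifnot(is.data.frame(weather))
  need <- c("tmax", "tmin", "rh", "wind", "srad", "doy")
  miss <- setdiff(need, names(weather))
  if (length(miss)) abort(paste("weather lacks columns:", paste(miss, collapse = ", ")))
  if (any(weather$tmin > weather$tmax + 1e-12)) abort("tmin > tmax in weather input")
  if (any(weather$rh < 0 | weather$rh > 100)) abort("rh must be within [0, 100]")

  et0 <- et0_penman_monteith(
    tmax = weather$tmax, tmin = weather$tmin, rh = weather$rh,
    wind = weather$wind, srad = weather$srad, doy = weather$doy,
    latitude = latitude, elevation = elevation, rn = net_radiation
  )
  dplyr::mutate(as_tibble(weather), et0 = et0)
}

# Vectorised FAO-56 computation on bare numeric inputs.
et0_penman_monteith <- function(tmax, tmin, rh, wind, srad, doy,
                                latitude, elevation = 0, rn = NULL) {
  tmean <- (tmax + tmin) / 2
  # Saturation vapour pressure (kPa), mean of values at tmax and tmin
  svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- es * rh / 100
  # Slope of the saturation curve at tmean (kPa/degC)
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  # Psychrometric constant from elevation-dependent pressure
  pressure <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pressure

  if (is.null(rn)) {
    rns <- (1 - 0.23) * srad
    ra <- extraterrestrial_radiation(latitude, doy)
    rso <- (0.75 + 2e-5 * elevation) * ra
    rel <- ifelse(rso > 0, pmin(pmax(srad / rso, 0.3), 1), 0.3)
    sigma <- 4.903e-9
    tk4 <- ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2
    rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
    rn <- rns - rnl
  }

  num <- 0.408 * delta * pmax(rn, 0) +
    gamma * (900 / (tmean + 273)) * wind * pmax(es - ea, 0)
  den <- delta + gamma * (1 + 0.34 * wind)
  pmax(num / den, 0)
}

# Extraterrestrial radiation Ra (MJ m-2 day-1), FAO-56 daily form.
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(dec), -1), 1)
  ws <- acos(x)
  gsc <- 0.0820
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}
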