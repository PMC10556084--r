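# Daily weather features for phenology modelling: thermal time (GDD),
# vapour pressure deficit and FAO-56 reference evapotranspiration.

#' Cumulative growing degree days
#'
#' Thermal time accumulated from the start of the series as
#' `sum(max(0, tmean - base))`, the standard GDD clock with a 10 degC base.
#'
#' @param weather `data.frame` with contiguous `date` and `tmean` columns.
#' @param base_c Base temperature, degC.
#' @return Numeric vector of cumulative GDD (degC day), aligned with the rows
#'   of `weather`; non-decreasing.
#' @export
#' @examples
#' w <- data.frame(date = as.Date("2022-01-01") + 0:2, tmean = c(12, 8, 15))
#' cumulative_gdd(w) # 2 2 7
cumulative_gdd <- function(weather, base_c = 10) {
  d <- weather$date
  if (length(d) > 1 && any(diff(d) != 1)) {
    stop("alignment error: weather series has gaps", call. = FALSE)
  }
  cumsum(pmax(0, weather$tmean - base_c))
}

# Tetens saturation vapour pressure, kPa at T degC
svp_kpa <- function(t_c) {
  0.6108 * exp(17.27 * t_c / (t_c + 237.3))
}

#' Daily vapour pressure deficit
#'
#' VPD from mean temperature and relative humidity using the Tetens
#' saturation vapour pressure curve: `es(T) * (1 - RH/100)`.
#'
#' @param tmean Mean air temperature, degC.
#' @param rh_pct Relative humidity, % in \[0, 100\].
#' @return VPD in kPa (multiply by 10 for hPa).
#' @export
#' @examples
#' daily_vpd(25, 50) # about 1.58 kPa
daily_vpd <- function(tmean, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100)) {
    stop("rh_pct must be in [0, 100]", call. = FALSE)
  }
  svp_kpa(tmean) * (1 - rh_pct / 100)
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere shortwave on a horizontal plane (FAO-56 Eq. 21 form),
#' used by the reference evapotranspiration calculation.
#'
#' @param latitude Degrees.
#' @param doy Day of year.
#' @return Radiation in MJ m^-2 day^-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily grass-reference ET0 from standard weather-station variables.
#' Net longwave uses the measured-to-clear-sky shortwave ratio; actual
#' vapour pressure comes from mean relative humidity.
#'
#' @param tmin,tmax Daily minimum / maximum air temperature, degC.
#' @param rh_pct Daily mean relative humidity, %.
#' @param wind Wind speed at 2 m, m s^-1.
#' @param radiation Incoming shortwave, MJ m^-2 day^-1.
#' @param latitude Degrees.
#' @param doy Day of year.
#' @param altitude_m Station altitude, m a.s.l.
#' @return ET0 in mm day^-1, floored at 0.
#' @export
reference_etp <- function(tmin, tmax, rh_pct, wind, radiation,
                          latitude, doy, altitude_m = 0) {
  tmean <- (tmin + tmax) / 2
  p_kpa <- 101.3 * ((293 - 0.0065 * altitude_m) / 293)^5.26
  gamma <- 0.000665 * p_kpa
  delta <- 4098 * svp_kpa(tmean) / (tmean + 237.3)^2
  es <- (svp_kpa(tmin) + svp_kpa(tmax)) / 2
  ea <- es * rh_pct / 100
  ra <- extraterrestrial_radiation(latitude, doy)
  rso <- (0.75 + 2e-5 * altitude_m) * ra
  rns <- (1 - 0.23) * radiation
  rel <- pmin(pmax(ifelse(rso > 0, radiation / rso, 0), 0.3), 1)
  sigma <- 4.903e-9
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl
  et0 <- (0.408 * delta * rn +
    gamma * 900 / (tmean + 273) * wind * (es - ea)) /
    (delta + gamma * (1 + 0.34 * wind))
  pmax(et0, 0)
}

#' Build the daily phenology feature table
#'
#' As-of-date features for every day of a site-year: cumulative GDD,
#' cumulative radiation and cumulative reference ET from 1 January, plus the
#' day's Tmax, Tmean, Tsoil (measured or, when absent, the previous day's
#' Tmean as a thermal-inertia proxy), VPD, RH, wind and precipitation.
#'
#' @param weather `data.frame` of daily records with columns `date`, `tmin`,
#'   `tmean`, `tmax`, `rh_pct`, `wind`, `radiation`, `precip_mm` and
#'   optionally `tsoil`.
#' @param latitude Degrees (for ET0).
#' @param altitude_m Station altitude.
#' @param gdd_base_c GDD base temperature.
#' @return `data.frame` with `date`, `doy` and feature columns `gdd`,
#'   `cum_radiation`, `cum_etp`, `tmax`, `tmean`, `tsoil`, `vpd`, `rh`,
#'   `wind`, `precip`.
#' @export
phenology_features <- function(weather, latitude, altitude_m = 0,
                               gdd_base_c = 10) {
  doy <- as.integer(strftime(weather$date, "%j"))
  etp <- reference_etp(
    weather$tmin, weather$tmax, weather$rh_pct, weather$wind,
    weather$radiation, latitude, doy, altitude_m
  )
  tsoil <- if ("tsoil" %in% names(weather) && !all(is.na(weather$tsoil))) {
    weather$tsoil
  } else {
    c(weather$tmean[1], weather$tmean[-nrow(weather)])
  }
  data.frame(
    date = weather$date,
    doy = doy,
    gdd = cumulative_gdd(weather, gdd_base_c),
    cum_radiation = cumsum(weather$radiation),
    cum_etp = cumsum(etp),
    tmax = weather$tmax,
    tmean = weather$tmean,
    tsoil = tsoil,
    vpd = daily_vpd(weather$tmean, weather$rh_pct),
    rh = weather$rh_pct,
    wind = weather$wind,
    precip = weather$precip_mm
  )
}
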