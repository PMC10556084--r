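# Solar position, day length and clear-sky irradiance.
# All diurnal computations use local solar time; conversion from civil time
# is an I/O-layer concern (see read_weather / run configuration).

#' Conversion constants for irradiance units
#'
#' Energy-to-photon conversion used throughout: shortwave irradiance in
#' W m^-2 is converted to photosynthetic photon flux density (PPFD,
#' umol m^-2 s^-1) as `W * PAR_FRACTION * UMOL_PER_J_PAR`. 4.6 umol J^-1 is
#' the standard daylight conversion for the PAR waveband; 0.45 is the PAR
#' fraction of total shortwave.
#'
#' @format Named numeric constants.
#' @export
UMOL_PER_J_PAR <- 4.6

#' @rdname UMOL_PER_J_PAR
#' @export
PAR_FRACTION <- 0.45

#' Solar declination
#'
#' Declination of the sun for a given day of year, computed with the Spencer
#' Fourier series (accurate to about 0.01 degrees, verified against the NOAA
#' solar calculator to within 0.5 degrees in the test suite).
#'
#' @param doy Day of year, 1-based from 1 January (1..366).
#' @return Declination in degrees, in \[-23.6, 23.6\].
#' @export
#' @examples
#' solar_declination(172) # close to +23.4 at the June solstice
solar_declination <- function(doy) {
  if (any(doy < 1 | doy > 366)) {
    stop("doy must be in [1, 366]", call. = FALSE)
  }
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  decl * 180 / pi
}

#' Solar position (elevation, azimuth, hour angle)
#'
#' Sun elevation and azimuth for a site and instant in local solar time.
#' Azimuth is measured clockwise from north in \[0, 360).
#'
#' @param latitude Latitude in degrees (positive north), |latitude| <= 90.
#' @param longitude Longitude in degrees (positive east). Unused by the solar
#'   trigonometry itself (time is already solar) but kept on the record so
#'   downstream callers carry the full site description.
#' @param doy Day of year.
#' @param local_solar_time Hours since solar midnight (12 = solar noon).
#' @return Object of class `solar_angles`: list with `declination`,
#'   `elevation`, `azimuth`, `hour_angle` (all degrees).
#' @export
solar_position <- function(latitude, longitude = 0, doy, local_solar_time) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90", call. = FALSE)
  decl <- solar_declination(doy)
  h <- 15 * (local_solar_time - 12) # hour angle, degrees, negative morning
  phi <- latitude * pi / 180
  dr <- decl * pi / 180
  hr <- h * pi / 180
  sin_el <- sin(phi) * sin(dr) + cos(phi) * cos(dr) * cos(hr)
  sin_el <- pmin(1, pmax(-1, sin_el))
  el <- asin(sin_el)
  # azimuth from north, clockwise; cos formula + morning/afternoon branch
  cos_az <- (sin(dr) - sin_el * sin(phi)) / (cos(el) * cos(phi))
  cos_az[!is.finite(cos_az)] <- 1 # sun at zenith: azimuth degenerate
  cos_az <- pmin(1, pmax(-1, cos_az))
  az <- acos(cos_az) * 180 / pi
  az <- ifelse(h > 0, 360 - az, az) %% 360
  structure(
    list(
      declination = decl,
      elevation = el * 180 / pi,
      azimuth = az,
      hour_angle = h
    ),
    class = "solar_angles"
  )
}

#' @export
print.solar_angles <- function(x, ...) {
  cat(sprintf(
    "solar angles: elevation %.2f deg, azimuth %.2f deg (decl %.2f, HA %.1f)\n",
    x$elevation[1], x$azimuth[1], x$declination[1], x$hour_angle[1]
  ))
  invisible(x)
}

#' Astronomical day length
#'
#' Hours the sun spends above a configurable altitude threshold. The default
#' threshold of -0.833 degrees accounts for atmospheric refraction plus the
#' solar half-disc, the convention under which sunrise/sunset tables are
#' published.
#'
#' @param latitude Latitude in degrees.
#' @param doy Day of year.
#' @param sun_altitude_threshold Altitude defining sunrise/sunset (degrees).
#' @return Day length in hours, in \[0, 24\] (24 under midnight sun, 0 in
#'   polar night).
#' @export
#' @examples
#' day_length(45.1, 171) # about 15.63 h (15 h 38 min) near the solstice
day_length <- function(latitude, doy, sun_altitude_threshold = -0.833) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90", call. = FALSE)
  decl <- solar_declination(doy)
  phi <- latitude * pi / 180
  dr <- decl * pi / 180
  h0 <- sun_altitude_threshold * pi / 180
  cos_ha <- (sin(h0) - sin(phi) * sin(dr)) / (cos(phi) * cos(dr))
  ifelse(cos_ha <= -1, 24,
    ifelse(cos_ha >= 1, 0, 2 * acos(cos_ha) * 180 / pi / 15)
  )
}

#' Sunrise and sunset in local solar time
#'
#' @inheritParams day_length
#' @return Numeric vector `c(sunrise, sunset)` in solar hours.
#' @export
sun_rise_set <- function(latitude, doy, sun_altitude_threshold = -0.833) {
  dl <- day_length(latitude, doy, sun_altitude_threshold)
  c(sunrise = 12 - dl / 2, sunset = 12 + dl / 2)
}

#' Clear-sky irradiance components
#'
#' Simple transmittance / air-mass clear-sky model returning direct-normal,
#' direct-horizontal and diffuse-horizontal photon flux. Direct-normal
#' irradiance is the extraterrestrial flux attenuated as
#' `clearness ^ airmass` (Kasten-Young air mass, altitude-corrected);
#' diffuse is a fixed fraction of the direct-horizontal beam. This stands in
#' for measured incident light when the tool is run without a radiometer.
#'
#' @param angles A `solar_angles` object (see [solar_position()]).
#' @param doy Day of year (for the sun-earth distance correction).
#' @param altitude_m Site altitude in m a.s.l.
#' @param clearness Atmospheric transmittance per unit air mass (0-1).
#' @param diffuse_fraction Diffuse-to-direct-horizontal ratio.
#' @return Object of class `irradiance_components`: list with `direct_normal`,
#'   `direct_horizontal`, `diffuse_horizontal` (umol m^-2 s^-1) and the
#'   `angles` used.
#' @export
clear_sky_components <- function(angles, doy, altitude_m = 0,
                                 clearness = 0.72, diffuse_fraction = 0.18) {
  el <- angles$elevation
  e0 <- 1367 * (1 + 0.033 * cos(2 * pi * doy / 365)) # W m^-2, extraterrestrial
  up <- el > 0
  am <- rep(Inf, length(el))
  am[up] <- 1 / (sin(el[up] * pi / 180) +
    0.50572 * (el[up] + 6.07995)^(-1.6364))
  am <- am * exp(-altitude_m / 8434.5) # pressure-scaled air mass
  dni_w <- ifelse(up, e0 * clearness^am, 0)
  to_umol <- UMOL_PER_J_PAR * PAR_FRACTION
  dni <- dni_w * to_umol
  dir_h <- ifelse(up, dni * sin(el * pi / 180), 0)
  dif_h <- diffuse_fraction * dir_h
  structure(
    list(
      direct_normal = dni,
      direct_horizontal = dir_h,
      diffuse_horizontal = dif_h,
      angles = angles
    ),
    class = "irradiance_components"
  )
}

#' Direct-beam irradiance on a tilted surface
#'
#' Direct component intercepted by a plane of given azimuth and tilt
#' (0 = horizontal, 90 = vertical), zero at or beyond grazing incidence.
#'
#' @param components An `irradiance_components` object.
#' @param angles A `solar_angles` object (defaults to the one stored in
#'   `components`).
#' @param surface_azimuth Azimuth the surface normal faces, degrees from north.
#' @param surface_tilt Tilt from horizontal in degrees, in \[0, 90\].
#' @param total If `TRUE`, add the isotropic diffuse contribution
#'   `diffuse_horizontal * (1 + cos(tilt)) / 2` and return the plane total.
#' @return Irradiance on the plane in umol m^-2 s^-1.
#' @export
irradiance_on_surface <- function(components, angles = components$angles,
                                  surface_azimuth, surface_tilt,
                                  total = FALSE) {
  if (any(surface_tilt < 0 | surface_tilt > 90)) {
    stop("surface_tilt must be in [0, 90]", call. = FALSE)
  }
  el <- angles$elevation * pi / 180
  az <- angles$azimuth * pi / 180
  beta <- surface_tilt * pi / 180
  gam <- surface_azimuth * pi / 180
  cos_inc <- cos(el) * sin(beta) * cos(az - gam) + sin(el) * cos(beta)
  direct <- components$direct_normal * pmax(0, cos_inc)
  direct[angles$elevation <= 0] <- 0
  if (!total) {
    return(direct)
  }
  direct + components$diffuse_horizontal * (1 + cos(beta)) / 2
}
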