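# Row-shadow canopy light interception.
# The vine row is modelled as an opaque rectangular slab (trained vertical
# wall), infinitely long; total canopy light interception (TCLI, %) is the
# ratio of the under-canopy shaded band to the alley width, clamped at 100%
# when the shadow spans the full between-row spacing.

#' Vineyard geometry descriptor
#'
#' Site, row and canopy dimensions driving the shadow model.
#'
#' @param latitude,longitude Site coordinates in degrees.
#' @param altitude Altitude in m a.s.l.
#' @param row_azimuth Azimuth of the row axis in degrees; rows are axial so
#'   the value is reduced modulo 180.
#' @param row_spacing Between-row spacing in m; must exceed `canopy_width`.
#' @param canopy_height Canopy wall height in m (above `canopy_base_height`).
#' @param canopy_width Canopy thickness across the row in m.
#' @param canopy_base_height Height of the canopy base above ground in m. On
#'   flat ground the base offset shifts the shadow band sideways without
#'   widening it, so it does not enter the shaded fraction.
#' @param slope Ground slope in degrees.
#' @param aspect Downslope azimuth in degrees.
#' @return Object of class `vineyard_geometry`.
#' @export
#' @examples
#' g <- vineyard_geometry(45.1, 9.6, row_azimuth = 35, row_spacing = 2.5,
#'                        canopy_height = 2.2, canopy_width = 0.5)
vineyard_geometry <- function(latitude, longitude = 0, altitude = 0,
                              row_azimuth, row_spacing, canopy_height,
                              canopy_width, canopy_base_height = 0.6,
                              slope = 0, aspect = 0) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90", call. = FALSE)
  if (canopy_width <= 0 || canopy_height <= 0) {
    stop("canopy dimensions must be positive", call. = FALSE)
  }
  if (row_spacing <= canopy_width) {
    stop("row_spacing must exceed canopy_width (degenerate geometry)",
      call. = FALSE
    )
  }
  structure(
    list(
      latitude = latitude, longitude = longitude, altitude = altitude,
      row_azimuth = row_azimuth %% 180,
      row_spacing = row_spacing,
      canopy_height = canopy_height,
      canopy_width = canopy_width,
      canopy_base_height = canopy_base_height,
      slope = slope, aspect = aspect
    ),
    class = "vineyard_geometry"
  )
}

#' @export
print.vineyard_geometry <- function(x, ...) {
  cat(sprintf(
    paste0(
      "vineyard geometry: %.3f N %.3f E, %g m a.s.l.\n",
      "  rows az %g deg, spacing %.2f m; canopy %.2f x %.2f m (base %.2f m)\n",
      "  slope %g deg, aspect %g deg\n"
    ),
    x$latitude, x$longitude, x$altitude, x$row_azimuth, x$row_spacing,
    x$canopy_height, x$canopy_width, x$canopy_base_height, x$slope, x$aspect
  ))
  invisible(x)
}

# Sun elevation/azimuth in the terrain-aligned frame: rotate the sun unit
# vector by -slope about the horizontal axis perpendicular to the aspect
# direction. Identity on flat ground.
terrain_sun <- function(geometry, angles) {
  if (geometry$slope == 0) {
    return(list(elevation = angles$elevation, azimuth = angles$azimuth))
  }
  el <- angles$elevation * pi / 180
  az <- angles$azimuth * pi / 180
  asp <- geometry$aspect * pi / 180
  s <- geometry$slope * pi / 180
  # ENU components rotated so x points downslope
  x <- cos(el) * cos(az - asp)
  y <- cos(el) * sin(az - asp)
  z <- sin(el)
  xs <- x * cos(s) + z * sin(s)
  zs <- -x * sin(s) + z * cos(s)
  list(
    elevation = asin(pmin(1, pmax(-1, zs))) * 180 / pi,
    azimuth = ((atan2(y, xs) * 180 / pi) + geometry$aspect) %% 360
  )
}

#' Cross-row shadow band width
#'
#' Width of the shadow band cast across the alley by the opaque canopy slab,
#' per unit row length: `canopy_width + canopy_height * cot(elevation) *
#' |sin(sun_azimuth - row_azimuth)|`. The width equals the canopy width when
#' the sun is at the zenith or its azimuth is parallel to the row.
#'
#' @param geometry A `vineyard_geometry`.
#' @param angles A `solar_angles` for the instant of interest.
#' @return Shadow width in m (`NA` when the sun is below the horizon; callers
#'   treat night as full cover). Uncapped: compare with `row_spacing` via
#'   [shaded_fraction()].
#' @export
shadow_width <- function(geometry, angles) {
  sun <- terrain_sun(geometry, angles)
  el <- sun$elevation
  daz <- (sun$azimuth - geometry$row_azimuth) * pi / 180
  w <- geometry$canopy_width +
    geometry$canopy_height / tan(el * pi / 180) * abs(sin(daz))
  w[el <= 0] <- NA_real_
  w
}

#' Shaded fraction of the alley
#'
#' @param width Shadow band width in m (from [shadow_width()]).
#' @param geometry A `vineyard_geometry`.
#' @return `min(width / row_spacing, 1)`; `NA` width (night) maps to 1
#'   (full cover, no direct beam reaches the alley floor).
#' @export
shaded_fraction <- function(width, geometry) {
  if (any(width < 0, na.rm = TRUE)) stop("width must be >= 0", call. = FALSE)
  f <- pmin(width / geometry$row_spacing, 1)
  f[is.na(width)] <- 1
  f
}

#' Diurnal TCLI profile
#'
#' Total canopy light interception from sunrise to sunset on a regular solar
#' time grid. TCLI (%) is 100 x the shaded fraction; it is pinned at 100%
#' whenever the shadow spans the full alley, which for typical row geometries
#' happens at low sun angles early and late in the day.
#'
#' @param geometry A `vineyard_geometry`.
#' @param doy Day of year.
#' @param time_step Grid step in minutes, in \[1, 120\].
#' @return `data.frame` of class `tcli_profile` with columns `time` (solar
#'   hours), `elevation`, `azimuth`, `shadow_width_m`, `shaded_fraction`,
#'   `tcli_percent`.
#' @export
#' @examples
#' g <- vineyard_geometry(45.1, 9.6, row_azimuth = 35, row_spacing = 2.5,
#'                        canopy_height = 2.2, canopy_width = 0.5)
#' prof <- tcli_profile(g, doy = 201, time_step = 30)
#' range(prof$tcli_percent)
tcli_profile <- function(geometry, doy, time_step = 30) {
  if (time_step < 1 || time_step > 120) {
    stop("time_step must be in [1, 120] minutes", call. = FALSE)
  }
  rs <- sun_rise_set(geometry$latitude, doy)
  times <- seq(rs[["sunrise"]], rs[["sunset"]], by = time_step / 60)
  ang <- solar_position(geometry$latitude, geometry$longitude, doy, times)
  w <- shadow_width(geometry, ang)
  f <- shaded_fraction(w, geometry)
  out <- data.frame(
    time = times,
    elevation = ang$elevation,
    azimuth = ang$azimuth,
    shadow_width_m = w,
    shaded_fraction = f,
    tcli_percent = 100 * f
  )
  class(out) <- c("tcli_profile", "data.frame")
  out
}
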