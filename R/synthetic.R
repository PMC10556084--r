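# Seeded synthetic data: weather series, vineyard configurations, phenology
# events and transpiration observations with the statistical structure the
# pipeline assumes. Defaults emulate a northern-Italian hillside vineyard
# climate (temperate, summer-dry spells, ~45 N).

#' Weather generator parameters
#'
#' @param latitude Site latitude, degrees.
#' @param altitude_m Site altitude, m a.s.l.
#' @param tmean_annual Annual mean temperature, degC.
#' @param tmean_amplitude Half-range of the annual temperature sinusoid,
#'   degC (peak minus annual mean).
#' @param tmean_phase Day of year of the warmest day.
#' @param diurnal_amplitude Mean daily tmax - tmin, degC.
#' @param noise_sd Day-to-day temperature noise SD, degC.
#' @param clearness_shape1,clearness_shape2 Beta parameters of the daily
#'   clearness index (fraction of clear-sky radiation reaching the ground).
#' @param precip_prob Daily precipitation occurrence probability.
#' @param precip_shape,precip_scale Gamma parameters of wet-day amounts, mm.
#' @param rh_base Mean relative humidity on dry days, %.
#' @param rh_sd Humidity noise SD, %.
#' @param wind_mean Mean wind speed, m s^-1.
#' @param seed Integer seed.
#' @return Object of class `weather_gen_params`.
#' @export
weather_gen_params <- function(latitude = 45.1, altitude_m = 100,
                               tmean_annual = 13.5, tmean_amplitude = 10.5,
                               tmean_phase = 200, diurnal_amplitude = 9,
                               noise_sd = 2,
                               clearness_shape1 = 5, clearness_shape2 = 1.8,
                               precip_prob = 0.25, precip_shape = 0.9,
                               precip_scale = 8,
                               rh_base = 65, rh_sd = 8, wind_mean = 2,
                               seed = 1) {
  stopifnot(
    noise_sd >= 0, rh_sd >= 0, precip_prob >= 0, precip_prob <= 1,
    diurnal_amplitude >= 0
  )
  structure(
    as.list(environment()),
    class = "weather_gen_params"
  )
}

#' Generate a year of synthetic weather
#'
#' Daily series (temperature sinusoid plus AR-free Gaussian noise,
#' beta-distributed clearness scaling a clear-sky radiation integral,
#' two-state precipitation occurrence with gamma amounts, humidity raised on
#' wet days) plus a 30-minute sub-daily grid of temperature, VPD and direct
#' light whose daily aggregates match the daily series by construction.
#'
#' @param params A [weather_gen_params()].
#' @param year Calendar year (drives the date column and leap handling).
#' @param subdaily_step Sub-daily grid step in minutes.
#' @param subdaily Set `FALSE` to skip the sub-daily grid (faster when only
#'   daily series are needed).
#' @return List with `daily` (date, doy, tmin, tmean, tmax, rh_pct, wind,
#'   radiation MJ m^-2 d^-1, precip_mm) and `subdaily` (date, doy, time,
#'   temp_c, vpd_hpa, direct_light umol m^-2 s^-1; `NULL` when skipped).
#' @export
gen_weather <- function(params, year = 2022, subdaily_step = 30,
                        subdaily = TRUE) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
    as.Date(sprintf("%d-12-31", year)),
    by = 1
  )
  n <- length(dates)
  doy <- seq_len(n)
  withr::with_seed(params$seed, {
    tmean <- params$tmean_annual +
      params$tmean_amplitude * cos(2 * pi * (doy - params$tmean_phase) / 365) +
      stats::rnorm(n, 0, params$noise_sd)
    kt <- stats::rbeta(n, params$clearness_shape1, params$clearness_shape2)
    wet <- stats::runif(n) < params$precip_prob
    precip <- ifelse(
      wet, stats::rgamma(n, params$precip_shape, scale = params$precip_scale), 0
    )
    kt[wet] <- kt[wet] * 0.5 # overcast on rain days
    rh <- pmin(100, pmax(
      5,
      params$rh_base + 20 * wet + stats::rnorm(n, 0, params$rh_sd)
    ))
    wind <- pmax(0.1, stats::rgamma(n, 4, scale = params$wind_mean / 4))
  })
  half_d <- params$diurnal_amplitude / 2
  tmin <- tmean - half_d
  tmax <- tmean + half_d
  # clear-sky daily shortwave integral, MJ m^-2 day^-1, scaled by clearness
  rad <- vapply(doy, function(d) {
    hrs <- seq(0, 24, by = 0.5)
    ang <- solar_position(params$latitude, 0, d, hrs)
    comp <- clear_sky_components(ang, d, params$altitude_m)
    w_m2 <- comp$direct_horizontal / (UMOL_PER_J_PAR * PAR_FRACTION) *
      (1 + 0.18)
    sum(w_m2) * 0.5 * 3600 / 1e6
  }, numeric(1)) * kt
  daily <- data.frame(
    date = dates, doy = doy,
    tmin = tmin, tmean = tmean, tmax = tmax,
    rh_pct = rh, wind = wind, radiation = rad, precip_mm = precip
  )
  if (!subdaily) {
    return(list(daily = daily, subdaily = NULL))
  }
  # sub-daily grid: zero-mean diurnal cosine (coldest 02:00, warmest 14:00)
  tod <- seq(0, 24 - subdaily_step / 60, by = subdaily_step / 60)
  shape <- cos(2 * pi * (tod - 14) / 24)
  sub <- do.call(rbind, lapply(seq_len(n), function(i) {
    ang <- solar_position(params$latitude, 0, doy[i], tod)
    comp <- clear_sky_components(ang, doy[i], params$altitude_m)
    temp <- tmean[i] + half_d * shape
    data.frame(
      date = dates[i], doy = doy[i], time = tod,
      temp_c = temp,
      vpd_hpa = 10 * daily_vpd(temp, rep(rh[i], length(tod))),
      direct_light = comp$direct_horizontal * kt[i]
    )
  }))
  list(daily = daily, subdaily = sub)
}

#' Generative truth parameters for synthetic experiments
#'
#' @param gdd_thresholds Named stage thresholds in degC day (must be
#'   increasing budburst < flowering < veraison). Defaults place the events
#'   inside the standard stage search windows for the default climate; the
#'   low budburst threshold mirrors the small, highly variable heat sums at
#'   which swollen buds appear.
#' @param jitter_sd SD of the integer day jitter added to the GDD-crossing
#'   event date.
#' @param tc_coefficients True six-term quadratic transpiration
#'   coefficients (named as in [tc_model()]).
#' @param tc_noise_sd Transpiration observation noise SD as a fraction of
#'   the signal's SD.
#' @param soil `list(sand_pct, clay_pct, om_pct, depth_m)` truth.
#' @return Object of class `truth_params`.
#' @export
truth_params <- function(gdd_thresholds = c(
                           budburst = 30, flowering = 420, veraison = 1150
                         ),
                         jitter_sd = 2,
                         tc_coefficients = c(
                           x1_sq = 7.62563e-09, x2_sq = 0.0104358,
                           x3_sq = 1.49096e-06, x1_x2 = -7.72001e-06,
                           x1_x3 = 1.07106e-07, x2_x3 = -0.000129436
                         ),
                         tc_noise_sd = 0.05,
                         soil = list(
                           sand_pct = 30, clay_pct = 35, om_pct = 1.2,
                           depth_m = 1
                         )) {
  if (is.unsorted(gdd_thresholds, strictly = TRUE)) {
    stop("stage thresholds must increase budburst < flowering < veraison",
      call. = FALSE
    )
  }
  structure(
    list(
      gdd_thresholds = gdd_thresholds, jitter_sd = jitter_sd,
      tc_coefficients = tc_coefficients, tc_noise_sd = tc_noise_sd,
      soil = soil
    ),
    class = "truth_params"
  )
}

#' Generate phenology events from a GDD-threshold rule
#'
#' The true event day is the first day on which cumulative GDD (base 10)
#' reaches the stage threshold, plus rounded Gaussian jitter. Stages whose
#' threshold is never reached are marked missing (`NA`).
#'
#' @param weather Daily weather (`$daily` of [gen_weather()] or equivalent).
#' @param truth A [truth_params()].
#' @param seed Integer seed for the jitter.
#' @return `data.frame` with `stage`, `crossing_doy`, `event_doy`.
#' @export
gen_phenology <- function(weather, truth, seed = 1) {
  gdd <- cumulative_gdd(weather)
  stages <- names(truth$gdd_thresholds)
  crossing <- vapply(truth$gdd_thresholds, function(th) {
    i <- which(gdd >= th)
    if (length(i) == 0) NA_integer_ else as.integer(i[1])
  }, integer(1))
  jit <- withr::with_seed(
    seed,
    as.integer(round(stats::rnorm(length(stages), 0, truth$jitter_sd)))
  )
  event <- crossing + ifelse(is.na(crossing), NA_integer_, jit)
  event <- pmin(pmax(event, 1L), nrow(weather))
  data.frame(
    stage = stages,
    crossing_doy = crossing,
    event_doy = event
  )
}

#' Generate synthetic whole-canopy transpiration observations
#'
#' Evaluates the true quadratic at aligned (direct light, VPD, TCLI) grids
#' and adds Gaussian noise scaled to the signal, clamped at zero, emulating
#' chamber records.
#'
#' @param truth A [truth_params()].
#' @param tcli_profile A [tcli_profile()].
#' @param weather_subdaily Sub-daily grid with `time`, `direct_light`,
#'   `vpd_hpa` on the same time grid.
#' @param seed Integer seed.
#' @return `data.frame` of observations: `time`, `x1`, `x2`, `x3`, `y`
#'   (mmol H2O s^-1).
#' @export
gen_tc_observations <- function(truth, tcli_profile, weather_subdaily,
                                seed = 1) {
  if (nrow(tcli_profile) != nrow(weather_subdaily) ||
    max(abs(tcli_profile$time - weather_subdaily$time)) > 1e-6) {
    stop("alignment error: TCLI and weather grids differ", call. = FALSE)
  }
  m <- tc_model("quadratic", c("x1", "x2", "x3"), truth$tc_coefficients)
  mu <- predict_tc(
    m,
    x1 = weather_subdaily$direct_light,
    x2 = weather_subdaily$vpd_hpa,
    x3 = tcli_profile$tcli_percent
  )
  mu <- as.numeric(mu)
  noise_sd <- truth$tc_noise_sd * stats::sd(mu)
  y <- withr::with_seed(
    seed,
    pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
  )
  data.frame(
    time = tcli_profile$time,
    x1 = weather_subdaily$direct_light,
    x2 = weather_subdaily$vpd_hpa,
    x3 = tcli_profile$tcli_percent,
    y = y
  )
}

#' Sample a realistic vineyard configuration
#'
#' Uniform draws inside the envelopes spanned by trained-wall vineyards of
#' the region: between-row spacing 2.0-3.4 m, canopy height 0.9-1.4 m,
#' canopy width 0.30-0.50 m, altitude 27-430 m, one of the four common row
#' orientations, clay-loam textures.
#'
#' @param seed Integer seed.
#' @return List with `geometry` ([vineyard_geometry()]), `soil`
#'   ([pedotransfer()]) and `floor` ([floor_management()]).
#' @export
gen_vineyard <- function(seed = 1) {
  withr::with_seed(seed, {
    spacing <- stats::runif(1, 2.0, 3.4)
    height <- stats::runif(1, 0.9, 1.4)
    width <- stats::runif(1, 0.30, 0.50)
    alt <- stats::runif(1, 27, 430)
    lat <- stats::runif(1, 44, 45)
    lon <- stats::runif(1, 9, 11)
    az <- sample(c(0, 90, 45, 135), 1) # NS, EW, NE-SW, NW-SE
    sand <- stats::runif(1, 15, 40)
    clay <- stats::runif(1, 28, 42)
    om <- stats::runif(1, 0.8, 2.5)
    grass_frac <- stats::runif(1, 0.5, 0.8)
  })
  geometry <- vineyard_geometry(
    latitude = lat, longitude = lon, altitude = alt,
    row_azimuth = az, row_spacing = spacing,
    canopy_height = height, canopy_width = width
  )
  soil <- pedotransfer(sand, clay, om, depth_m = 1)
  floor <- floor_management(
    zones = data.frame(
      cover_class = c("winter_cover_crop", "tilled"),
      area_fraction = c(grass_frac, 1 - grass_frac)
    ),
    termination_date = as.Date("2022-05-19")
  )
  list(geometry = geometry, soil = soil, floor = floor)
}

#' Generate a cohort of synthetic site-years with phenology truth
#'
#' Draws per-site-year weather parameters (annual mean and amplitude vary
#' across sites, emulating the altitude/latitude spread of a regional
#' vineyard network), generates a year of weather each, applies the
#' GDD-threshold phenology rule and stacks the feature tables.
#'
#' @param n_site_years Number of site-years.
#' @param truth A [truth_params()].
#' @param seed Integer root seed; every site-year seed derives from it.
#' @param year Base calendar year.
#' @return List with `feature_table` (stacked [phenology_features()] with
#'   `site_year`), `events` (site_year, stage, crossing_doy, event_doy) and
#'   `weather` (named list of daily series).
#' @export
gen_site_years <- function(n_site_years = 40, truth = truth_params(),
                           seed = 1, year = 2022) {
  site_seeds <- withr::with_seed(
    seed, sample.int(1e6, n_site_years)
  )
  feats <- list()
  evs <- list()
  wx <- list()
  for (i in seq_len(n_site_years)) {
    s <- site_seeds[i]
    pars <- withr::with_seed(s, {
      weather_gen_params(
        latitude = stats::runif(1, 44, 45.5),
        altitude_m = stats::runif(1, 27, 430),
        tmean_annual = stats::rnorm(1, 13.5, 1.2),
        tmean_amplitude = stats::rnorm(1, 10.5, 0.8),
        noise_sd = 2,
        seed = s + 1
      )
    })
    w <- gen_weather(pars, year = year, subdaily = FALSE)
    id <- sprintf("SY%02d", i)
    ft <- phenology_features(w$daily, pars$latitude, pars$altitude_m)
    ft$site_year <- id
    ev <- gen_phenology(w$daily, truth, seed = s + 2)
    ev$site_year <- id
    feats[[i]] <- ft
    evs[[i]] <- ev
    wx[[id]] <- w$daily
  }
  list(
    feature_table = do.call(rbind, feats),
    events = do.call(rbind, evs),
    weather = wx
  )
}
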