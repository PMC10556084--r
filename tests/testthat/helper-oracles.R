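# Independent oracles used across the suite. Each reimplements the quantity
# it checks from a different formulation than the package code.

# NOAA solar-calculator algorithm (Julian-century polynomial series for the
# sun's apparent longitude and obliquity), independent of the Spencer series
# used by the package. Returns declination, elevation and azimuth (degrees,
# unrefracted) for local solar time.
noaa_solar <- function(lat, doy, hour, year = 2022) {
  date <- as.Date(sprintf("%d-01-01", year)) + (doy - 1)
  jd <- as.numeric(date) + 2440587.5 + hour / 24
  jc <- (jd - 2451545) / 36525
  rad <- pi / 180
  l0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  c <- sin(m * rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * rad) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * rad)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * rad)
  decl <- asin(sin(obliq * rad) * sin(app_long * rad)) / rad
  ha <- 15 * (hour - 12)
  sin_el <- sin(lat * rad) * sin(decl * rad) +
    cos(lat * rad) * cos(decl * rad) * cos(ha * rad)
  el <- asin(pmin(1, pmax(-1, sin_el))) / rad
  cos_az <- (sin(decl * rad) - sin_el * sin(lat * rad)) /
    (cos(el * rad) * cos(lat * rad))
  az <- acos(pmin(1, pmax(-1, cos_az))) / rad
  if (ha > 0) az <- 360 - az
  list(declination = decl, elevation = el, azimuth = az %% 360)
}

# Brute-force AUC: fraction of (positive, negative) score pairs ranked
# concordantly, ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Shadow of an opaque rectangular slab cross-section by corner projection:
# each corner (x, z) of the cross-row section lands at x + z * cot(el) *
# sin(az_sun - az_row); the band width is the extent over all corners.
shadow_width_projection <- function(canopy_width, canopy_height, base_height,
                                    elevation, sun_azimuth, row_azimuth) {
  shift <- 1 / tan(elevation * pi / 180) *
    sin((sun_azimuth - row_azimuth) * pi / 180)
  zs <- c(base_height, base_height + canopy_height)
  xs <- c(0, canopy_width)
  landing <- as.vector(outer(xs, zs, function(x, z) x + z * shift))
  max(landing) - min(landing)
}

# Evaluate the six-term quadratic directly (plain arithmetic, no design
# matrix machinery).
quad6 <- function(cf, x1, x2, x3) {
  cf[["x1_sq"]] * x1^2 + cf[["x2_sq"]] * x2^2 + cf[["x3_sq"]] * x3^2 +
    cf[["x1_x2"]] * x1 * x2 + cf[["x1_x3"]] * x1 * x3 +
    cf[["x2_x3"]] * x2 * x3
}

# Small helper: noiseless design for transpiration fitting tests.
tc_design_points <- function(n = 20, seed = 99) {
  withr::with_seed(seed, data.frame(
    x1 = runif(n, 0, 1800),
    x2 = runif(n, 0, 40),
    x3 = runif(n, 10, 100)
  ))
}
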