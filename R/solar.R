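#' Solar position (NOAA algorithm)
#'
#' Apparent solar declination, equation of time and geometric solar
#' elevation from the NOAA solar calculator algorithm (Julian-century
#' polynomials for the mean longitude, mean anomaly, eccentricity and
#' obliquity; equation of center; apparent longitude with nutation
#' correction).
#'
#' @param time POSIXct (UTC) vector.
#' @param latitude,longitude degrees (east/north positive); scalars or
#'   vectors matching `time`.
#' @return data.frame with `declination` (deg), `eqtime` (minutes),
#'   `hour_angle` (deg) and `elevation` (deg, geometric — no refraction
#'   applied; the day/night threshold absorbs refraction).
#' @export
solar_position <- function(time, latitude, longitude) {
  time <- as_utc(time)
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + T * 0.0003032)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C <- sin(M * d2r) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * T) +
    sin(3 * M * d2r) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 - T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r)) / d2r
  y <- tan(eps / 2 * d2r)^2
  eqtime <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * e * sin(M * d2r) +
    4 * e * y * sin(M * d2r) * cos(2 * L0 * d2r) -
    0.5 * y^2 * sin(4 * L0 * d2r) - 1.25 * e^2 * sin(2 * M * d2r))
  minutes <- (as.numeric(time) %% 86400) / 60
  tst <- (minutes + eqtime + 4 * longitude) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360
  sin_el <- sin(latitude * d2r) * sin(decl * d2r) +
    cos(latitude * d2r) * cos(decl * d2r) * cos(ha * d2r)
  data.frame(declination = decl, eqtime = eqtime, hour_angle = ha,
             elevation = asin(pmin(pmax(sin_el, -1), 1)) / d2r)
}

#' Classify a timestamp as day or night
#'
#' DAY when the apparent solar elevation is at or above -0.833 degrees
#' (the standard sunrise/sunset threshold: atmospheric refraction plus the
#' solar radius), NIGHT otherwise — so civil twilight is classed as night.
#' The boundary is closed on the day side.
#'
#' @inheritParams solar_position
#' @return character vector of `"day"` / `"night"`.
#' @export
classify_day_night <- function(time, latitude, longitude) {
  if (any(abs(latitude) > 66.5))
    stop2("polar latitudes (|lat| > 66.5) are not supported: ",
          "the day/night partition is undefined under midnight sun / polar night")
  el <- solar_position(time, latitude, longitude)$elevation
  ifelse(el >= -0.833, "day", "night")
}
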