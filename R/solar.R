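# Solar geometry via the NOAA solar-position equations (Meeus-style
# truncation). Evaluated once per civil date at 12:00 UTC, which keeps all
# phase instants within ~1 min of a full iterative solution -- ample for
# 10-min burst cadences.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Core NOAA quantities for a Julian century `tc`:
# equation of time (minutes) and solar declination (degrees).
noaa_eot_decl <- function(tc) {
  l0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  m  <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  ec <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)
  ceq <- sin(deg2rad(m)) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * tc) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + ceq
  omega <- 125.04 - 1934.136 * tc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  e0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- e0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(l0)) - 2 * ec * sin(deg2rad(m)) +
      4 * ec * y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * y^2 * sin(4 * deg2rad(l0)) - 1.25 * ec^2 * sin(2 * deg2rad(m))
  )
  list(eot = eot, decl = decl)
}

# Hour angle (degrees) at which the sun crosses `zenith` degrees.
hour_angle <- function(lat, decl, zenith) {
  cos_ha <- cos(deg2rad(zenith)) / (cos(deg2rad(lat)) * cos(deg2rad(decl))) -
    tan(deg2rad(lat)) * tan(deg2rad(decl))
  rad2deg(acos(pmin(1, pmax(-1, cos_ha))))
}

#' Solar phases for a date and site
#'
#' Computes dawn, sunrise, solar noon, sunset and dusk (all UTC) for one or
#' more civil dates at a site, using the NOAA solar-position equations.
#' Sunrise/sunset use the standard refracted zenith of 90.833 degrees; dawn
#' and dusk are civil twilight (zenith 96 degrees).
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @param lat,lon site latitude and longitude in decimal degrees
#'   (longitude positive east). Latitudes poleward of 66 degrees are
#'   rejected: polar day/night is not handled.
#' @return a data frame with one row per date and POSIXct (UTC) columns
#'   `dawn`, `sunrise`, `solar_noon`, `sunset`, `dusk`, always satisfying
#'   `dawn < sunrise < solar_noon < sunset < dusk`.
#' @examples
#' solar_phases(as.Date("2023-01-15"), lat = 39.0, lon = -76.2)
#' @export
solar_phases <- function(date, lat, lon) {
  date <- as.Date(date)
  if (!is.finite(lat) || !is.finite(lon) || abs(lat) > 90 || abs(lon) > 180) {
    stop_db("invalid site coordinates: lat=", lat, ", lon=", lon)
  }
  if (abs(lat) >= 66) {
    stop_db("latitudes poleward of 66 degrees are unsupported (polar day/night)")
  }
  jd_noon <- as.numeric(date) + 2440587.5 + 0.5
  tc <- (jd_noon - 2451545) / 36525
  sol <- noaa_eot_decl(tc)
  noon_min <- 720 - 4 * lon - sol$eot
  ha_sun <- hour_angle(lat, sol$decl, 90.833)
  ha_civil <- hour_angle(lat, sol$decl, 96)
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  out <- data.frame(
    date = date,
    dawn = day0 + 60 * (noon_min - 4 * ha_civil),
    sunrise = day0 + 60 * (noon_min - 4 * ha_sun),
    solar_noon = day0 + 60 * noon_min,
    sunset = day0 + 60 * (noon_min + 4 * ha_sun),
    dusk = day0 + 60 * (noon_min + 4 * ha_civil)
  )
  out
}

#' Assign timestamps to the diurnal or nocturnal period
#'
#' A timestamp is diurnal iff it falls in the half-open interval
#' `[sunrise, sunset)` of its own UTC calendar date at the site; every other
#' instant (including both crepuscular windows) is nocturnal, so the two
#' periods partition time.
#'
#' @param timestamp POSIXct vector (UTC).
#' @param lat,lon site coordinates in decimal degrees.
#' @param solar optional precomputed [solar_phases()] table covering every
#'   date in `timestamp`; computed on the fly when `NULL`.
#' @return character vector, `"diurnal"` or `"nocturnal"`, one per timestamp.
#' @export
assign_period <- function(timestamp, lat = NULL, lon = NULL, solar = NULL) {
  timestamp <- as_utc(timestamp)
  dates <- as.Date(timestamp, tz = "UTC")
  if (is.null(solar)) {
    if (is.null(lat) || is.null(lon)) {
      stop_db("assign_period() needs either `solar` or site lat/lon")
    }
    solar <- solar_phases(unique(dates), lat, lon)
  }
  idx <- match(dates, solar$date)
  if (anyNA(idx)) {
    stop_db("solar table does not cover date(s): ",
            paste(unique(format(dates[is.na(idx)])), collapse = ", "))
  }
  diurnal <- timestamp >= solar$sunrise[idx] & timestamp < solar$sunset[idx]
  ifelse(diurnal, "diurnal", "nocturnal")
}

#' Daylight duration in hours
#'
#' Sunset minus sunrise for each date, in hours; the multiplier used when
#' extrapolating mean hourly energy expenditure to a daylight-only daily
#' value.
#'
#' @inheritParams solar_phases
#' @return numeric vector of daylight hours.
#' @export
daylight_hours <- function(date, lat, lon) {
  ph <- solar_phases(date, lat, lon)
  as.numeric(difftime(ph$sunset, ph$sunrise, units = "hours"))
}
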