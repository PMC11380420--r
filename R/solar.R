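# Solar geometry (NOAA low-accuracy ephemeris) and diel period labelling.
# All times are UTC; a single reference coordinate is used for the whole
# cohort, mirroring common practice for coastal deployments.

.DEG <- pi / 180

# Fourier-series approximations for equation of time (minutes) and solar
# declination (radians), as functions of fractional year.
.solar_coefs <- function(doy, hour_utc) {
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  list(
    eqtime = 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                         0.014615 * cos(2 * g) - 0.040849 * sin(2 * g)),
    decl = 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  )
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon (degrees, unrefracted) at given
#' instants and coordinate, from the NOAA solar position equations.
#'
#' @param times POSIXct vector (UTC).
#' @param lat,lon Coordinate in decimal degrees.
#' @return Numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(times, lat, lon) {
  stopifnot(abs(lat) <= 90)
  lt <- as.POSIXlt(times, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  sc <- .solar_coefs(doy, hour)
  tst <- hour * 60 + sc$eqtime + 4 * lon
  ha <- (tst / 4 - 180) * .DEG
  latr <- lat * .DEG
  cosz <- sin(latr) * sin(sc$decl) + cos(latr) * cos(sc$decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cosz))) / .DEG
}

# Event times (minutes UTC from midnight) where the sun crosses the given
# zenith angle; NA when the sun never reaches it on that date.
.sun_crossings <- function(dates, lat, lon, zenith_deg) {
  doy <- as.POSIXlt(dates, tz = "UTC")$yday + 1
  sc <- .solar_coefs(doy, rep(12, length(doy)))
  latr <- lat * .DEG
  cosha <- cos(zenith_deg * .DEG) / (cos(latr) * cos(sc$decl)) -
    tan(latr) * tan(sc$decl)
  ha <- acos(ifelse(abs(cosha) <= 1, cosha, NA)) / .DEG
  list(rise = 720 - 4 * (lon + ha) - sc$eqtime,
       set  = 720 - 4 * (lon - ha) - sc$eqtime)
}

#' Sunrise, sunset and nautical twilight times
#'
#' Computes, per calendar date, sunrise/sunset (solar elevation -0.833
#' degrees, the standard refraction-corrected horizon) and nautical
#' dawn/dusk (elevation -12 degrees) for a coordinate.  Events that do not
#' occur on a date (polar day/night, bright high-latitude summer nights)
#' are returned as `NA` rather than raising an error.
#'
#' @param dates Date vector (or anything coercible via [as.Date()]).
#' @param lat,lon Coordinate in decimal degrees; defaults to the reference
#'   coordinate 60.3N, 5.2E used throughout the package.
#' @return A data.frame with one row per date and POSIXct (UTC) columns
#'   `nautical_dawn`, `sunrise`, `sunset`, `nautical_dusk`, plus the
#'   coordinate and a `polar_day` logical (sun above horizon all day).
#' @examples
#' sun_times(as.Date("2021-12-21"))
#' @export
sun_times <- function(dates, lat = 60.3, lon = 5.2) {
  stopifnot(abs(lat) <= 90)
  dates <- as.Date(dates)
  midnight <- as.POSIXct(paste(format(dates), "00:00:00"), tz = "UTC")
  sun <- .sun_crossings(dates, lat, lon, 90.833)
  naut <- .sun_crossings(dates, lat, lon, 102)
  to_time <- function(minutes) midnight + minutes * 60
  noon_elev <- solar_elevation(midnight + 12 * 3600, lat, lon)
  out <- data.frame(
    date = dates,
    nautical_dawn = to_time(naut$rise),
    sunrise = to_time(sun$rise),
    sunset = to_time(sun$set),
    nautical_dusk = to_time(naut$set),
    latitude = lat,
    longitude = lon,
    polar_day = is.na(sun$rise) & noon_elev > -0.833
  )
  class(out) <- c("diel_times", "data.frame")
  out
}

#' Classify timestamps into diel periods
#'
#' Labels each instant as day/night (2-level scheme, bounded by sunrise and
#' sunset) or dawn/day/dusk/night (4-level scheme, adding nautical dawn and
#' dusk).  Intervals are half-open and lower-inclusive: day is
#' `[sunrise, sunset)`, dawn `[nautical_dawn, sunrise)`, dusk
#' `[sunset, nautical_dusk)`, night the remainder.  When nautical events are
#' undefined (bright summer nights at high latitude) dawn/dusk are empty and
#' the 4-level scheme degrades to the 2-level one.  During polar day all
#' samples are "day"; during polar night all are "night".
#'
#' @param times POSIXct vector (UTC).
#' @param diel_times A table from [sun_times()] covering every date in
#'   `times` (an error is raised otherwise).
#' @param scheme 2 or 4.
#' @return Character vector of labels.
#' @export
classify_diel <- function(times, diel_times, scheme = 4) {
  stopifnot(scheme %in% c(2, 4))
  d <- as.Date(times, tz = "UTC")
  idx <- match(d, diel_times$date)
  if (anyNA(idx)) {
    stop("classify_diel: some timestamps fall on dates absent from `diel_times`")
  }
  sr <- diel_times$sunrise[idx]
  ss <- diel_times$sunset[idx]
  lab <- rep("night", length(times))
  day <- !is.na(sr) & times >= sr & times < ss
  lab[day] <- "day"
  polar <- is.na(sr) & diel_times$polar_day[idx]
  lab[polar] <- "day"
  if (scheme == 4) {
    nd <- diel_times$nautical_dawn[idx]
    nk <- diel_times$nautical_dusk[idx]
    dawn <- !is.na(nd) & !is.na(sr) & times >= nd & times < sr
    dusk <- !is.na(nk) & !is.na(ss) & times >= ss & times < nk
    lab[dawn] <- "dawn"
    lab[dusk] <- "dusk"
  }
  lab
}
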