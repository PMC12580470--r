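# Solar geometry: NOAA-style low-precision ephemeris, nautical-twilight
# day/night classification, and the sunrise/sunset-anchored solar-time
# transform used for circular activity analysis.

# Study-area reference coordinates (Bavarian Forest centroid) and the
# civil clock used to define calendar days. The park spans < 0.5 degrees,
# so one reference location shifts sun times by under two minutes.
DIEL_REF_LAT <- 49.0
DIEL_REF_LON <- 13.4
DIEL_REF_TZ <- "Etc/GMT-1"

# Altitude conventions: rise/set at -0.833 deg (refraction + half-disc),
# nautical twilight at exactly -12 deg.
RISE_SET_ALT <- -0.833
NAUTICAL_ALT <- -12

#' Sun altitude above the horizon
#'
#' Geometric altitude of the sun centre, from the NOAA low-accuracy solar
#' ephemeris (fractional-year expansion of declination and the equation of
#' time). Accuracy is a few hundredths of a degree, i.e. well under the
#' half-degree needed to place twilight crossings to the minute.
#'
#' @param lat,lon Latitude and longitude in decimal degrees (north/east
#'   positive).
#' @param instant `POSIXct` instant(s); any timezone (converted to UTC
#'   internally).
#' @return Numeric vector of altitudes in degrees above the horizon.
#' @export
#' @examples
#' noon <- as.POSIXct("2021-06-21 12:00:00", tz = "UTC")
#' sun_altitude(49, 13.4, noon)
sun_altitude <- function(lat, lon, instant) {
  stopifnot(is.numeric(lat), is.numeric(lon), abs(lat) <= 90)
  t <- as.POSIXlt(instant, tz = "UTC")
  doy <- t$yday
  hour <- t$hour + t$min / 60 + t$sec / 3600
  # fractional year, radians
  g <- 2 * pi / 365 * (doy + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g)) # minutes
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g) # radians
  # true solar time in minutes (UTC hour + equation of time + longitude)
  tst <- hour * 60 + eqtime + 4 * lon
  ha <- (tst / 4 - 180) * pi / 180 # hour angle, radians
  latr <- lat * pi / 180
  cos_zen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  90 - acos(cos_zen) * 180 / pi
}

# Refine one altitude crossing between two bracketing instants (numeric
# seconds since epoch) to ~1 s with uniroot.
.refine_crossing <- function(lat, lon, t_lo, t_hi, target_alt) {
  f <- function(s) {
    sun_altitude(lat, lon, as.POSIXct(s, origin = "1970-01-01", tz = "UTC")) -
      target_alt
  }
  r <- stats::uniroot(f, lower = t_lo, upper = t_hi, tol = 1)
  as.POSIXct(r$root, origin = "1970-01-01", tz = "UTC")
}

# Find all up/down crossings of a target altitude within [t0, t1).
.find_crossings <- function(lat, lon, t0, t1, target_alt, step = 120) {
  s <- seq(as.numeric(t0), as.numeric(t1), by = step)
  alt <- sun_altitude(lat, lon, as.POSIXct(s, origin = "1970-01-01", tz = "UTC"))
  f <- alt - target_alt
  idx <- which(f[-length(f)] * f[-1] < 0)
  up <- down <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  for (i in idx) {
    cr <- .refine_crossing(lat, lon, s[i], s[i + 1], target_alt)
    if (f[i] < 0) up <- c(up, cr) else down <- c(down, cr)
  }
  list(up = up, down = down)
}

#' Sunrise, sunset and nautical twilight for one date
#'
#' Locates the instants at which the sun crosses -0.833 degrees (rise/set)
#' and the requested twilight depression (default 12 degrees, nautical) on
#' a given civil date, by root-finding on the altitude function.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @param date A `Date` (or string coercible to one): the civil date in
#'   timezone `tz`.
#' @param depression Twilight depression angle below the horizon, degrees.
#' @param tz Timezone defining the civil day; defaults to the study clock
#'   (UTC+1).
#' @return A list with `date`, `lat`, `lon`, and `POSIXct` instants
#'   `sunrise`, `sunset`, `nautical_dawn_end`, `nautical_dusk_start`.
#' @export
twilight_times <- function(lat, lon, date, depression = 12,
                           tz = DIEL_REF_TZ) {
  date <- as.Date(date)
  day_start <- as.POSIXct(paste(date, "00:00:00"), tz = tz)
  day_end <- day_start + 86400
  rs <- .find_crossings(lat, lon, day_start, day_end, RISE_SET_ALT)
  tw <- .find_crossings(lat, lon, day_start, day_end, -abs(depression))
  if (length(rs$up) < 1 || length(rs$down) < 1 ||
    length(tw$up) < 1 || length(tw$down) < 1) {
    stop("no sunrise/sunset or twilight crossing on ", date,
      " at latitude ", lat, call. = FALSE
    )
  }
  list(
    date = date, lat = lat, lon = lon,
    sunrise = rs$up[1], sunset = rs$down[1],
    nautical_dawn_end = tw$up[1], nautical_dusk_start = tw$down[1]
  )
}

# Cached per-date sun times to avoid recomputing for event streams.
.sun_cache <- new.env(parent = emptyenv())

.sun_times_cached <- function(lat, lon, date, tz) {
  key <- paste(format(date), signif(lat, 7), signif(lon, 7), tz, sep = "|")
  if (!is.null(.sun_cache[[key]])) {
    return(.sun_cache[[key]])
  }
  st <- twilight_times(lat, lon, date, tz = tz)
  .sun_cache[[key]] <- st
  st
}

#' Night classification by nautical twilight
#'
#' An instant is night if it lies in the half-open interval from the onset
#' of evening nautical twilight to the end of morning nautical twilight
#' (sun below -12 degrees going down, until back above -12 going up). The
#' boundary instants themselves classify as: dawn end -> day, dusk start
#' -> night.
#'
#' @param instant `POSIXct` instant(s).
#' @param lat,lon Coordinates, defaulting to the study-area reference.
#' @param tz Civil timezone used to pick the calendar day.
#' @return Logical vector, `TRUE` for night.
#' @export
is_night <- function(instant, lat = DIEL_REF_LAT, lon = DIEL_REF_LON,
                     tz = DIEL_REF_TZ) {
  dates <- as.Date(format(instant, tz = tz, format = "%Y-%m-%d"))
  out <- logical(length(instant))
  for (d in unique(dates)) {
    st <- .sun_times_cached(lat, lon, as.Date(d, origin = "1970-01-01"), tz)
    i <- which(dates == d)
    ti <- as.numeric(instant[i])
    out[i] <- ti < as.numeric(st$nautical_dawn_end) |
      ti >= as.numeric(st$nautical_dusk_start)
  }
  out
}

#' Clock time to sunrise/sunset-anchored solar radians
#'
#' Double-anchored ("equinoctial") solar-time transform: for each civil
#' date, clock time is mapped piecewise linearly so that sunrise falls at
#' pi/2 and sunset at 3*pi/2, with the night interval stretched linearly
#' between sunset and the next sunrise. The result is a circular time in
#' `[0, 2*pi)` that removes the seasonal shift of day length, so activity
#' densities from different months are comparable.
#'
#' @param instant `POSIXct` instant(s).
#' @param lat,lon Coordinates, defaulting to the study-area reference.
#' @param tz Civil timezone used to pick the calendar day.
#' @return Numeric vector of solar radian times in `[0, 2*pi)`.
#' @export
to_solar_radians <- function(instant, lat = DIEL_REF_LAT,
                             lon = DIEL_REF_LON, tz = DIEL_REF_TZ) {
  dates <- as.Date(format(instant, tz = tz, format = "%Y-%m-%d"))
  out <- numeric(length(instant))
  for (d in unique(dates)) {
    dd <- as.Date(d, origin = "1970-01-01")
    st <- .sun_times_cached(lat, lon, dd, tz)
    i <- which(dates == d)
    ti <- as.numeric(instant[i])
    theta <- numeric(length(ti))
    rise <- as.numeric(st$sunrise)
    set <- as.numeric(st$sunset)
    day_i <- ti >= rise & ti <= set
    theta[day_i] <- pi / 2 + pi * (ti[day_i] - rise) / (set - rise)
    late <- ti > set
    if (any(late)) {
      nxt <- .sun_times_cached(lat, lon, dd + 1, tz)
      theta[late] <- 3 * pi / 2 + pi * (ti[late] - set) /
        (as.numeric(nxt$sunrise) - set)
    }
    early <- ti < rise
    if (any(early)) {
      prv <- .sun_times_cached(lat, lon, dd - 1, tz)
      pset <- as.numeric(prv$sunset)
      theta[early] <- 3 * pi / 2 + pi * (ti[early] - pset) / (rise - pset)
    }
    out[i] <- theta %% (2 * pi)
  }
  out
}
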