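# Solar geometry via the NOAA low-precision equations (fractional-year
# Fourier series for declination and the equation of time), official zenith
# 90.833 deg (atmospheric refraction + solar radius). Accurate to ~1-2 min at
# mid-latitudes, which is ample for 2-h diel periods.

.official_zenith_deg <- 90.833

noaa_terms <- function(doy) {
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime_min = eqtime, decl_rad = decl)
}

#' Official sunrise and sunset for a site and date
#'
#' NOAA solar-position equations at the official zenith of 90.833 degrees.
#' Vectorized over dates (and latitude/longitude of equal length).
#'
#' @param latitude,longitude Decimal degrees (longitude positive east).
#'   Latitudes within the polar circles (|lat| >= 66) are rejected: the
#'   sunrise/sunset construction is undefined under polar day or night.
#' @param date `Date` vector.
#' @return Tibble `date`, `sunrise`, `sunset` (POSIXct, UTC).
#' @export
#' @examples
#' solar_events(43.1, -6.3, as.Date("2021-06-15"))
solar_events <- function(latitude, longitude, date) {
  date <- as.Date(date)
  n <- max(length(date), length(latitude), length(longitude))
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  date <- rep_len(date, n)
  if (any(abs(latitude) >= 66)) {
    stop("unsupported latitude: |latitude| must be < 66 degrees ",
      "(polar day/night not handled)",
      call. = FALSE
    )
  }
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  tr <- noaa_terms(doy)
  lat_r <- latitude * pi / 180
  cos_ha <- cos(.official_zenith_deg * pi / 180) / (cos(lat_r) * cos(tr$decl_rad)) -
    tan(lat_r) * tan(tr$decl_rad)
  if (any(abs(cos_ha) > 1)) {
    stop("sun never rises/sets on the requested date(s)", call. = FALSE)
  }
  ha_deg <- acos(cos_ha) * 180 / pi
  day0 <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  sunrise_min <- 720 - 4 * (longitude + ha_deg) - tr$eqtime_min
  sunset_min <- 720 - 4 * (longitude - ha_deg) - tr$eqtime_min
  tibble::tibble(
    date = date,
    sunrise = day0 + sunrise_min * 60,
    sunset = day0 + sunset_min * 60
  )
}

#' Day length in hours
#'
#' @inheritParams solar_events
#' @return Numeric vector of daylight hours (official sunrise to sunset).
#' @export
day_length_hours <- function(latitude, longitude, date) {
  se <- solar_events(latitude, longitude, date)
  as.numeric(difftime(se$sunset, se$sunrise, units = "hours"))
}

#' Classify a timestamp into the four diel periods
#'
#' Periods tile the 24-h clock day with half-open intervals `[lo, hi)`:
#' sunrise = 1 h before to 1 h after official sunrise; day = 1 h after
#' sunrise to 1 h before sunset; sunset = 1 h before to 1 h after official
#' sunset; night = everything else (evening night is attributed to the
#' calendar date of its evening portion).
#'
#' @param timestamp POSIXct (UTC), on the same calendar date as the solar
#'   events supplied.
#' @param sunrise,sunset POSIXct official sunrise/sunset for that date
#'   (recycled as needed).
#' @return Character vector: `"sunrise"`, `"day"`, `"sunset"` or `"night"`.
#' @export
classify_period <- function(timestamp, sunrise, sunset) {
  t <- as.numeric(timestamp)
  sr <- rep_len(as.numeric(sunrise), length(t))
  ss <- rep_len(as.numeric(sunset), length(t))
  dplyr::case_when(
    t >= sr - 3600 & t < sr + 3600 ~ "sunrise",
    t >= sr + 3600 & t < ss - 3600 ~ "day",
    t >= ss - 3600 & t < ss + 3600 ~ "sunset",
    TRUE ~ "night"
  )
}

#' Hours of the clock day spent in each diel period
#'
#' @param sunrise,sunset POSIXct official solar events of one day (vectors
#'   allowed; recycled to common length).
#' @return Tibble with columns `sunrise`, `day`, `sunset`, `night` (hours,
#'   summing to 24 per row).
#' @export
period_durations <- function(sunrise, sunset) {
  dl <- as.numeric(difftime(sunset, sunrise, units = "hours"))
  tibble::tibble(
    sunrise = rep_len(2, length(dl)),
    day = dl - 2,
    sunset = 2,
    night = 24 - dl - 2
  )
}

#' Sun-relative continuous time on the [-1, +1] scale
#'
#' Removes seasonal day-length variation by re-expressing clock time through
#' a five-anchor piecewise-linear map that considers both sunrise and sunset:
#' solar midnight maps to -1/+1, official sunrise to -0.5, solar noon (the
#' sunrise/sunset midpoint) to 0, and official sunset to +0.5. The map is
#' continuous and strictly increasing over the diel cycle; timestamps falling
#' before the date's solar midnight are wrapped onto the adjacent cycle.
#'
#' @param timestamp POSIXct (UTC).
#' @param sunrise,sunset POSIXct official solar events of the timestamp's
#'   date (recycled).
#' @return Numeric vector in `[-1, 1)`.
#' @export
sun_relative_time <- function(timestamp, sunrise, sunset) {
  t <- as.numeric(timestamp)
  sr <- rep_len(as.numeric(sunrise), length(t))
  ss <- rep_len(as.numeric(sunset), length(t))
  noon <- (sr + ss) / 2
  m0 <- noon - 43200
  m1 <- noon + 43200
  t <- t + 86400 * (t < m0) - 86400 * (t >= m1)
  dplyr::case_when(
    t < sr ~ -1 + 0.5 * (t - m0) / (sr - m0),
    t < noon ~ -0.5 + 0.5 * (t - sr) / (noon - sr),
    t < ss ~ 0.5 * (t - noon) / (ss - noon),
    TRUE ~ 0.5 + 0.5 * (t - ss) / (m1 - ss)
  )
}

#' Invert the sun-relative time map
#'
#' @param sun_time Numeric in `[-1, 1)`.
#' @param sunrise,sunset POSIXct official solar events of the target date.
#' @return POSIXct timestamps (UTC) whose [sun_relative_time()] equals
#'   `sun_time`.
#' @export
clock_from_sun_time <- function(sun_time, sunrise, sunset) {
  u <- sun_time
  sr <- rep_len(as.numeric(sunrise), length(u))
  ss <- rep_len(as.numeric(sunset), length(u))
  noon <- (sr + ss) / 2
  m0 <- noon - 43200
  m1 <- noon + 43200
  t <- dplyr::case_when(
    u < -0.5 ~ m0 + (u + 1) / 0.5 * (sr - m0),
    u < 0 ~ sr + (u + 0.5) / 0.5 * (noon - sr),
    u < 0.5 ~ noon + u / 0.5 * (ss - noon),
    TRUE ~ ss + (u - 0.5) / 0.5 * (m1 - ss)
  )
  as.POSIXct(t, tz = "UTC", origin = "1970-01-01")
}

#' Day-of-year (ecological Julian date)
#'
#' @param timestamp POSIXct or Date.
#' @return Integer day of year (1 for 1 January; 365 for 31 December 2021).
#' @export
julian_date <- function(timestamp) {
  lubridate::yday(timestamp)
}

#' Annotate events with solar and calendar time variables
#'
#' Joins each event to its site's coordinates, computes official sunrise and
#' sunset for the event date, and derives the diel period, sun-relative time,
#' day-of-year and month, plus a `debark` flag (any visual-marking bout).
#'
#' @param events Events tibble.
#' @param sites Site metadata (one or more rows per site; coordinates are
#'   taken from the first row per site).
#' @return Tibble: `event_id`, `site_id`, `start`, `class`, `period`,
#'   `sun_time`, `julian_date`, `month`, `sunrise`, `sunset`, `debark`,
#'   `marking`.
#' @export
annotate_events <- function(events, sites) {
  coords <- sites %>%
    dplyr::distinct(.data$site_id, .keep_all = TRUE) %>%
    dplyr::select("site_id", "latitude", "longitude")
  missing <- setdiff(unique(events$site_id), coords$site_id)
  if (length(missing) > 0) {
    stop("events reference unknown site(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ann <- dplyr::left_join(
    events[, c("event_id", "site_id", "start", "class", "bouts")],
    coords,
    by = "site_id"
  )
  se <- solar_events(ann$latitude, ann$longitude, as.Date(ann$start, tz = "UTC"))
  fl <- behavior_flags(events, .behavior_codes)
  tibble::tibble(
    event_id = ann$event_id,
    site_id = ann$site_id,
    start = ann$start,
    class = ann$class,
    period = classify_period(ann$start, se$sunrise, se$sunset),
    sun_time = sun_relative_time(ann$start, se$sunrise, se$sunset),
    julian_date = julian_date(ann$start),
    month = lubridate::month(ann$start),
    sunrise = se$sunrise,
    sunset = se$sunset,
    debark = Reduce(`|`, fl[.visual_codes]),
    marking = Reduce(`|`, fl[.marking_codes])
  )
}

#' Camera-trap days of survey effort per month
#'
#' A camera-trap day is one calendar day of one deployed camera; any day
#' intersecting a deployment interval counts in full. Effort is the unit used
#' to correct capture counts for unequal exposure.
#'
#' @param sites Site metadata tibble (one row per deployment).
#' @param year Calendar year.
#' @return Tibble `month`, `camera_trap_days`.
#' @export
camera_trap_days <- function(sites, year) {
  months <- 1:12
  month_start <- as.Date(sprintf("%d-%02d-01", year, months))
  month_end <- lubridate::ceiling_date(month_start, "month") - 1
  days <- vapply(months, function(m) {
    tot <- 0L
    for (i in seq_len(nrow(sites))) {
      lo <- max(sites$deploy_start[i], month_start[m])
      hi <- min(sites$deploy_end[i], month_end[m])
      if (lo <= hi) tot <- tot + as.integer(hi - lo) + 1L
    }
    tot
  }, integer(1))
  tibble::tibble(month = months, camera_trap_days = days)
}

#' Monthly relative independent capture (RIC) index
#'
#' RIC = independent captures of the month / camera-trap days of the month
#' x 1000: a monthly capture rate standardized by survey effort.
#'
#' @param events Events tibble (the independent captures).
#' @param sites Site metadata tibble.
#' @param year Calendar year analysed.
#' @return Tibble `month`, `independent_captures`, `camera_trap_days`, `ric`
#'   (NA for undeployed months).
#' @export
compute_ric <- function(events, sites, year) {
  yr_events <- events[lubridate::year(events$start) == year, ]
  caps <- table(factor(lubridate::month(yr_events$start), levels = 1:12))
  eff <- camera_trap_days(sites, year)
  if (any(eff$camera_trap_days == 0 & as.integer(caps) > 0)) {
    bad <- which(eff$camera_trap_days == 0 & as.integer(caps) > 0)
    stop("month(s) with captures but zero camera-trap days: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    month = 1:12,
    independent_captures = as.integer(caps),
    camera_trap_days = eff$camera_trap_days,
    ric = ifelse(eff$camera_trap_days > 0,
      1000 * as.integer(caps) / eff$camera_trap_days, NA_real_
    )
  )
}

#' Actogram table of marking events
#'
#' One row per marking event: day of year, UTC hour (fractional), marking
#' type (`visual` when the event contains a visual-marking bout, otherwise
#' `chemical`), and the day's sunrise/sunset hours for overlay lines.
#'
#' @param events Events tibble.
#' @param sites Site metadata tibble.
#' @return Tibble `event_id`, `day_of_year`, `hour_utc`, `mark_type`,
#'   `sunrise_hour`, `sunset_hour`.
#' @export
build_actogram <- function(events, sites) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      event_id = character(), day_of_year = integer(), hour_utc = numeric(),
      mark_type = character(), sunrise_hour = numeric(), sunset_hour = numeric()
    ))
  }
  ann <- annotate_events(events, sites)
  mk <- ann[ann$marking, ]
  hour_of <- function(t) {
    lubridate::hour(t) + lubridate::minute(t) / 60 + lubridate::second(t) / 3600
  }
  tibble::tibble(
    event_id = mk$event_id,
    day_of_year = mk$julian_date,
    hour_utc = hour_of(mk$start),
    mark_type = ifelse(mk$debark, "visual", "chemical"),
    sunrise_hour = hour_of(mk$sunrise),
    sunset_hour = hour_of(mk$sunset)
  )
}

#' Summed diel-period exposure over deployed days
#'
#' For the exposure-corrected circadian goodness-of-fit test: total hours
#' each diel period contributed over every deployed camera-day, accounting
#' for seasonal day-length variation.
#'
#' @param sites Site metadata tibble.
#' @param year Calendar year.
#' @return Named numeric vector of hours for `sunrise`, `day`, `sunset`,
#'   `night`.
#' @export
period_exposure <- function(sites, year) {
  tot <- c(sunrise = 0, day = 0, sunset = 0, night = 0)
  yr_lo <- as.Date(sprintf("%d-01-01", year))
  yr_hi <- as.Date(sprintf("%d-12-31", year))
  for (i in seq_len(nrow(sites))) {
    lo <- max(sites$deploy_start[i], yr_lo)
    hi <- min(sites$deploy_end[i], yr_hi)
    if (lo > hi) next
    dates <- seq(lo, hi, by = "day")
    se <- solar_events(sites$latitude[i], sites$longitude[i], dates)
    pd <- period_durations(se$sunrise, se$sunset)
    tot <- tot + c(
      sunrise = sum(pd$sunrise), day = sum(pd$day),
      sunset = sum(pd$sunset), night = sum(pd$night)
    )
  }
  tot
}
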