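test_that("sunrise/sunset computations match almanac behavior", {
  # equinox at the equator: 12-h day within 10 min
  eq <- day_length_hours(0, 0, as.Date("2021-03-20"))
  expect_lt(abs(eq - 12), 10 / 60)

  # monotone seasonality at 43 N
  expect_gt(
    day_length_hours(43, -6, as.Date("2021-06-15")),
    day_length_hours(43, -6, as.Date("2021-12-15"))
  )

  # study area: ~9h21 daylight mid-January, ~15h18 mid-June (within 10 min)
  jan <- day_length_hours(43.1, -6.3, as.Date("2021-01-15"))
  jun <- day_length_hours(43.1, -6.3, as.Date("2021-06-15"))
  expect_lt(abs(jan - (9 + 21 / 60)), 10 / 60)
  expect_lt(abs(jun - (15 + 18 / 60)), 10 / 60)

  # seasonal amplitude at 43 N: monthly mean day length differs by ~6 h
  # between January and June (within 20 min)
  jan_days <- seq(as.Date("2021-01-01"), as.Date("2021-01-31"), by = "day")
  jun_days <- seq(as.Date("2021-06-01"), as.Date("2021-06-30"), by = "day")
  amp <- mean(day_length_hours(43.1, -6.3, jun_days)) -
    mean(day_length_hours(43.1, -6.3, jan_days))
  expect_lt(abs(amp - 6), 20 / 60)

  # independent check against geosphere's daylength model
  dates <- as.Date("2021-01-01") + seq(5, 360, by = 30)
  ours <- day_length_hours(43.1, -6.3, dates)
  ref <- geosphere::daylength(43.1, as.integer(strftime(dates, "%j")))
  expect_lt(max(abs(ours - ref)), 5 / 60)

  expect_error(solar_events(70, 20, as.Date("2021-06-21")), "unsupported latitude")
})

test_that("diel periods tile the clock day with 2-h sunrise/sunset windows", {
  day <- as.Date("2021-05-01")
  se <- solar_events(43.1, -6.3, day)
  at <- function(h) as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + h * 3600

  sr_h <- as.numeric(difftime(se$sunrise, at(0), units = "hours"))
  ss_h <- as.numeric(difftime(se$sunset, at(0), units = "hours"))
  expect_equal(classify_period(se$sunrise - 1800, se$sunrise, se$sunset), "sunrise")
  expect_equal(classify_period(se$sunset - 1800, se$sunrise, se$sunset), "sunset")
  expect_equal(classify_period(at(13), se$sunrise, se$sunset), "day")
  expect_equal(classify_period(at(0.5), se$sunrise, se$sunset), "night")
  # boundaries are half-open [lo, hi)
  expect_equal(classify_period(se$sunrise + 3600, se$sunrise, se$sunset), "day")
  expect_equal(classify_period(se$sunset + 3600, se$sunrise, se$sunset), "night")

  # the four periods partition every minute of the 24 h
  mins <- at(seq(0, 24, by = 1 / 60)[-1441])
  per <- classify_period(mins, se$sunrise, se$sunset)
  tab <- table(per) / 60
  expect_equal(unname(tab["sunrise"]), 2)
  expect_equal(unname(tab["sunset"]), 2)
  expect_equal(sum(tab), 24)
  pd <- period_durations(se$sunrise, se$sunset)
  expect_equal(unname(tab["day"]), pd$day, tolerance = 0.02)
  expect_equal(rowSums(pd), 24)
})

test_that("sun-relative time hits its anchors and is strictly monotone", {
  se <- solar_events(43.1, -6.3, as.Date("2021-08-10"))
  noon <- se$sunrise + as.numeric(difftime(se$sunset, se$sunrise, units = "secs")) / 2
  expect_equal(sun_relative_time(se$sunrise, se$sunrise, se$sunset), -0.5)
  expect_equal(sun_relative_time(se$sunset, se$sunrise, se$sunset), 0.5)
  expect_equal(sun_relative_time(noon, se$sunrise, se$sunset), 0)
  midnight0 <- noon - 43200
  expect_equal(sun_relative_time(midnight0, se$sunrise, se$sunset), -1)

  # strictly increasing and continuous across the cycle
  ts <- midnight0 + seq(0, 86399, by = 60)
  u <- sun_relative_time(ts, se$sunrise, se$sunset)
  expect_true(all(diff(u) > 0))
  expect_lt(max(diff(u)), 0.002)
  expect_true(all(u >= -1 & u < 1))

  # round trip through the inverse map
  uu <- seq(-1, 0.999, by = 0.05)
  back <- sun_relative_time(
    clock_from_sun_time(uu, se$sunrise, se$sunset),
    se$sunrise, se$sunset
  )
  expect_equal(back, uu, tolerance = 1e-9)
})

test_that("day-of-year Julian dates follow the ecological convention", {
  expect_equal(julian_date(as.Date("2021-01-01")), 1)
  expect_equal(julian_date(as.Date("2021-12-31")), 365)
  expect_equal(julian_date(as.Date("2021-05-01")), 121)
  expect_equal(julian_date(as.POSIXct("2021-05-01 18:00:00", tz = "UTC")), 121)
})

test_that("camera-trap days and RIC follow the effort formulas", {
  sites <- synthetic_sites(13, 2021)
  ctd <- camera_trap_days(sites, 2021)
  expect_equal(sum(ctd$camera_trap_days), 4745)
  expect_equal(ctd$camera_trap_days[1], 13 * 31)
  expect_equal(ctd$camera_trap_days[2], 13 * 28)

  # 13 sites deployed through a 31-day month, 10 events -> RIC 24.8
  t0 <- as.POSIXct("2021-05-10 12:00:00", tz = "UTC")
  ev <- dplyr::bind_rows(lapply(1:10, function(i) {
    fixture_event(paste0("e", i), "dorsal", start = t0 + i * 86400 * 2)
  }))
  ev$site_id <- "T01"
  ric <- compute_ric(ev, sites, 2021)
  expect_equal(ric$camera_trap_days[5], 403)
  expect_equal(round_half_up(ric$ric[5], 1), 24.8)
  expect_equal(ric$ric[2], 0)

  # linearity in captures, inverse proportionality in exposure
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, event_id = paste0(event_id, "b"), start = start + 3600))
  expect_equal(compute_ric(ev2, sites, 2021)$ric[5], 2 * ric$ric[5])
  expect_equal(compute_ric(ev, sites[1:4, ], 2021)$ric[5], ric$ric[5] * 13 / 4)

  # partial deployment: half of May at one site
  half <- fixture_site(from = "2021-05-01", to = "2021-05-16")
  expect_equal(camera_trap_days(half, 2021)$camera_trap_days[5], 16)

  # captures in an undeployed month are a data inconsistency
  jan_ev <- fixture_event("e1", "dorsal",
    start = as.POSIXct("2021-01-05 12:00:00", tz = "UTC")
  )
  expect_error(compute_ric(jan_ev, half, 2021), "zero camera-trap days")
})

test_that("actogram rows carry solar overlays and marking type", {
  sites <- fixture_site()
  ev <- fixture_event("e1", c("clawing", "dorsal"),
    start = as.POSIXct("2021-05-01 18:00:00", tz = "UTC")
  )
  act <- build_actogram(ev, sites)
  expect_equal(nrow(act), 1)
  expect_equal(act$day_of_year, 121)
  expect_equal(act$hour_utc, 18)
  expect_equal(act$mark_type, "visual")
  expect_true(all(act$sunrise_hour < act$sunset_hour))

  chem <- fixture_event("e2", "dorsal")
  expect_equal(build_actogram(chem, sites)$mark_type, "chemical")
  # investigation-only events are not marking rows
  inv <- fixture_event("e3", "investigation")
  expect_equal(nrow(build_actogram(inv, sites)), 0)
  expect_equal(nrow(build_actogram(ev[0, ], sites)), 0)
})

test_that("event annotation derives period, sun time and debark flags", {
  sites <- fixture_site()
  ev <- fixture_events(
    fixture_event("e1", c("dorsal", "clawing"),
      start = as.POSIXct("2021-05-01 19:30:00", tz = "UTC")
    ),
    fixture_event("e2", "investigation",
      start = as.POSIXct("2021-05-01 01:00:00", tz = "UTC")
    )
  )
  ann <- annotate_events(ev, sites)
  expect_equal(ann$debark, c(TRUE, FALSE))
  expect_equal(ann$marking, c(TRUE, FALSE))
  expect_equal(ann$julian_date, c(121, 121))
  expect_equal(ann$month, c(5, 5))
  expect_equal(ann$period[2], "night")
  expect_true(all(ann$sun_time >= -1 & ann$sun_time < 1))
  expect_error(
    annotate_events(dplyr::mutate(ev, site_id = "T99"), sites),
    "unknown site"
  )
})
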