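test_that("native CSV parsing maps rows to detections and validates the vocabulary", {
  path <- write_native_csv(c(
    "T01,2021-05-01T10:00:00Z,adult_male,dorsal,0,12,systematic,",
    "T01,2021-05-01T10:00:00Z,adult_male,investigation,13,4,systematic,"
  ))
  det <- parse_event_log(path)
  expect_equal(nrow(det), 1)
  expect_equal(nrow(det$bouts[[1]]), 2)
  expect_equal(det$bouts[[1]]$behavior, c("dorsal", "investigation"))
  expect_s3_class(det$start, "POSIXct")
  expect_equal(lubridate::tz(det$start), "UTC")

  single <- parse_event_log(write_native_csv(
    "T01,2021-05-01T10:00:00Z,adult_male,dorsal,0,12,systematic,"
  ))
  expect_equal(nrow(single), 1)
  expect_equal(nrow(single$bouts[[1]]), 1)

  empty <- parse_event_log(write_native_csv(character()))
  expect_equal(nrow(empty), 0)

  expect_error(
    parse_event_log(write_native_csv(
      "T01,2021-05-01T10:00:00Z,adult_male,jumping,0,12,systematic,"
    )),
    "allowed codes.*dorsal"
  )
})

test_that("schema and timestamp errors are reported precisely", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,timestamp_iso8601_utc,class,behavior,start_offset_s,duration_s,source",
    "T01,2021-05-01T10:00:00Z,adult_male,dorsal,0,12,systematic"
  ), path)
  expect_error(parse_event_log(path), "missing column.*mark_height")

  bad_ts <- write_native_csv(c(
    "T01,2021-05-01T10:00:00Z,adult_male,dorsal,0,12,systematic,",
    "T01,not-a-time,adult_male,dorsal,0,12,systematic,"
  ))
  expect_error(parse_event_log(bad_ts), "line\\(s\\): 3")
  expect_error(parse_event_log(tempfile()), "not found")
})

test_that("the native dialect round-trips losslessly", {
  path <- write_native_csv(c(
    "T01,2021-05-01T10:00:00Z,adult_male,dorsal,0,12.5,systematic,",
    "T01,2021-05-01T10:00:00Z,adult_male,clawing,14,6,systematic,above_shoulder",
    "T02,2021-06-03T21:15:30Z,subadult_female,investigation,2,8,opportunistic,"
  ))
  det <- parse_event_log(path)
  path2 <- tempfile(fileext = ".csv")
  write_event_log(det, path2)
  expect_equal(parse_event_log(path2), det)
})

test_that("the aggregated dialect with sidecar parses to the same detections", {
  agg <- tempfile(fileext = ".csv")
  writeLines(c(
    "Observation id,Subject,Behavior,Start (s),Stop (s)",
    "obs1,bear,dorsal,0,12",
    "obs1,bear,investigation,13,17"
  ), agg)
  sidecar <- tibble::tibble(
    observation_id = "obs1", site_id = "T01",
    timestamp_iso8601_utc = "2021-05-01T10:00:00Z",
    class = "adult_male", source = "systematic", mark_height = NA_character_
  )
  det <- parse_event_log(agg, dialect = "boris_aggregated", sidecar = sidecar)
  expect_equal(nrow(det), 1)
  expect_equal(det$bouts[[1]]$behavior, c("dorsal", "investigation"))
  expect_equal(det$bouts[[1]]$duration_s, c(12, 4))
  expect_error(
    parse_event_log(agg, dialect = "boris_aggregated"),
    "sidecar"
  )
})

test_that("independence filtering merges within-window detections per site", {
  t0 <- as.POSIXct("2021-05-01 10:00:00", tz = "UTC")
  det3 <- dplyr::bind_rows(
    fixture_event("d1", "dorsal", start = t0),
    fixture_event("d2", "investigation", start = t0 + 10 * 60),
    fixture_event("d3", "pedal", start = t0 + 40 * 60)
  )
  names(det3)[1] <- "detection_id"
  ev <- filter_independent_events(det3, 30)
  # d1+d2 merge (10-min gap); d3 starts a new event (30 min after d2)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$n_detections, c(2L, 1L))
  expect_equal(ev$bouts[[1]]$behavior, c("dorsal", "investigation"))
  # merged bout offsets are shifted by the detection delay
  expect_equal(ev$bouts[[1]]$start_offset_s[2], 600)

  two_sites <- dplyr::bind_rows(
    fixture_event("d1", "dorsal", start = t0, site_id = "T01"),
    fixture_event("d2", "dorsal", start = t0 + 5 * 60, site_id = "T02")
  )
  names(two_sites)[1] <- "detection_id"
  expect_equal(nrow(filter_independent_events(two_sites, 30)), 2)

  gap40 <- dplyr::bind_rows(
    fixture_event("d1", "dorsal", start = t0),
    fixture_event("d2", "dorsal", start = t0 + 40 * 60)
  )
  names(gap40)[1] <- "detection_id"
  expect_equal(nrow(filter_independent_events(gap40, 30)), 2)

  expect_warning(
    filter_independent_events(det3[c(2, 1, 3), ], 30),
    "not in time order"
  )
})

test_that("independence filtering is idempotent", {
  set.seed(11)
  t0 <- as.POSIXct("2021-04-01 00:00:00", tz = "UTC")
  for (rep in 1:5) {
    times <- t0 + sort(sample.int(5e5, 40))
    det <- dplyr::bind_rows(lapply(1:40, function(i) {
      fixture_event(
        sprintf("d%02d", i), sample(behavior_codes(), 2),
        start = times[i],
        site_id = sample(c("T01", "T02", "T03"), 1)
      )
    }))
    names(det)[1] <- "detection_id"
    once <- filter_independent_events(det, 30)
    again <- once
    names(again)[1] <- "detection_id"
    again$n_detections <- NULL
    twice <- filter_independent_events(again, 30)
    expect_equal(nrow(twice), nrow(once))
    expect_equal(twice$bouts, once$bouts)
  }
})

test_that("merge views recode bouts without collapsing", {
  eth <- bear_ethogram()
  ev <- fixture_event("e1", c("dorsal", "facial"))
  merged <- apply_merge(ev, eth, "chemical_view")
  expect_equal(merged$bouts[[1]]$behavior, c("rubbing", "rubbing"))

  ev2 <- fixture_event("e2", c("clawing", "biting"))
  expect_equal(
    apply_merge(ev2, eth, "visual_view")$bouts[[1]]$behavior,
    c("debarking", "debarking")
  )
  ev0 <- fixture_event("e0", character())
  expect_equal(nrow(apply_merge(ev0, eth, "chemical_view")$bouts[[1]]), 0)
  expect_error(apply_merge(ev, eth, "nope"), "available views")
})

test_that("behavior frequencies count events, not bouts", {
  all7 <- fixture_event("e1", behavior_codes())
  tb <- tabulate_behavior_frequencies(all7)
  expect_true(all(tb$percent == 100))

  four <- fixture_events(
    fixture_event("e1", "pedal"),
    fixture_event("e2", "dorsal"),
    fixture_event("e3", "dorsal"),
    fixture_event("e4", "investigation")
  )
  tb4 <- tabulate_behavior_frequencies(four)
  expect_equal(tb4$percent[tb4$behavior == "pedal"], 25)
  # repeated bouts of one behavior still count once per event
  rep_bouts <- fixture_event("e1", c("dorsal", "dorsal", "dorsal"))
  expect_equal(tabulate_behavior_frequencies(rep_bouts)$n_events, 1L)
  expect_error(tabulate_behavior_frequencies(four[0, ]), "empty event set")
})

test_that("class-by-behavior columns are class compositions summing to 100", {
  ev <- fixture_events(
    fixture_event("e1", c("dorsal", "clawing"), class = "adult_male"),
    fixture_event("e2", c("dorsal", "biting"), class = "adult_male"),
    fixture_event("e3", "dorsal", class = "adult_female"),
    fixture_event("e4", "investigation", class = "subadult_male")
  )
  tb <- tabulate_class_behavior(ev, "coarse")
  expect_equal(tb$visual_marking[tb$class == "adult_male"], 100)
  expect_true(all(tb$visual_marking[tb$class != "adult_male"] == 0))

  one <- fixture_event("e1", "investigation", class = "adult_female")
  tb1 <- tabulate_class_behavior(one, "coarse")
  expect_equal(tb1$investigation[tb1$class == "adult_female"], 100)

  uniform <- fixture_events(
    fixture_event("e1", "investigation", class = "adult_male"),
    fixture_event("e2", "investigation", class = "adult_female"),
    fixture_event("e3", "investigation", class = "subadult_male"),
    fixture_event("e4", "investigation", class = "cub")
  )
  tbu <- tabulate_class_behavior(uniform, "coarse")
  expect_equal(sort(tbu$investigation, decreasing = TRUE)[1:4], rep(25, 4))

  # property: every non-empty category column sums to 100 within 0.1
  set.seed(21)
  for (rep in 1:5) {
    evr <- dplyr::bind_rows(lapply(1:30, function(i) {
      fixture_event(
        sprintf("e%02d", i),
        sample(behavior_codes(), sample(1:4, 1)),
        class = sample(bear_classes("fine"), 1)
      )
    }))
    tbr <- tabulate_class_behavior(evr, "coarse")
    sums <- colSums(tbr[, -1])
    expect_true(all(abs(sums[sums > 0] - 100) < 0.1))
  }
})

test_that("duration summaries zero-fill absent behaviors", {
  one <- fixture_event("e1", "dorsal", durations = 10)
  d1 <- summarize_durations(one, "dorsal")
  expect_equal(d1$mean_s, 10)
  expect_equal(d1$sd_s, 0)
  expect_equal(d1$min_s, 10)

  two <- fixture_events(
    fixture_event("e1", "dorsal", durations = 10),
    fixture_event("e2", "investigation", durations = 4)
  )
  d2 <- summarize_durations(two, c("dorsal", "pedal"))
  expect_equal(d2$mean_s[d2$behavior == "dorsal"], 5)
  expect_equal(d2$min_s[d2$behavior == "dorsal"], 0)
  expect_equal(d2$max_s[d2$behavior == "dorsal"], 10)
  # never-observed behavior: all-zero row
  expect_equal(unlist(d2[d2$behavior == "pedal", c("mean_s", "sd_s", "min_s", "max_s")]),
    c(mean_s = 0, sd_s = 0, min_s = 0, max_s = 0)
  )
  expect_error(summarize_durations(two[0, ]), "empty")
})

test_that("mark-height tabulation splits above/below the shoulder line", {
  ev <- dplyr::bind_rows(
    lapply(1:15, function(i) {
      fixture_event(paste0("a", i), "clawing", mark_height = "above_shoulder")
    }),
    lapply(1:9, function(i) {
      fixture_event(paste0("b", i), "clawing", mark_height = "below_shoulder")
    })
  )
  mh <- tabulate_mark_heights(ev)
  expect_equal(mh$n_marks, 24)
  expect_equal(mh$percent_above, 62.5)
  expect_equal(mh$percent_below, 37.5)
  expect_equal(mh$percent_above + mh$percent_below, 100)

  one <- fixture_event("e1", "clawing", mark_height = "above_shoulder")
  expect_equal(tabulate_mark_heights(one)$percent_above, 100)

  even <- dplyr::bind_rows(
    fixture_event("e1", "clawing", mark_height = "above_shoulder"),
    fixture_event("e2", "clawing", mark_height = "above_shoulder"),
    fixture_event("e3", "clawing", mark_height = "below_shoulder"),
    fixture_event("e4", "clawing", mark_height = "below_shoulder")
  )
  expect_equal(tabulate_mark_heights(even)$percent_above, 50)
  no_marks <- fixture_event("e1", "dorsal")
  expect_error(tabulate_mark_heights(no_marks), "mark-height")
})
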