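# Small in-code fixtures shared across test files.

bout_tbl <- function(behaviors, offsets = NULL, durations = NULL) {
  if (is.null(durations)) durations <- rep(5, length(behaviors))
  if (is.null(offsets)) {
    offsets <- if (length(behaviors)) cumsum(c(0, utils::head(durations, -1) + 1)) else numeric()
  }
  tibble::tibble(
    behavior = as.character(behaviors),
    start_offset_s = as.numeric(offsets),
    duration_s = as.numeric(durations)
  )
}

fixture_event <- function(id, behaviors,
                          start = as.POSIXct("2021-05-01 12:00:00", tz = "UTC"),
                          site_id = "T01", class = "adult_male",
                          source = "systematic", mark_height = NA_character_,
                          durations = NULL) {
  tibble::tibble(
    event_id = id, site_id = site_id, start = start, class = class,
    source = source, mark_height = mark_height,
    bouts = list(bout_tbl(behaviors, durations = durations))
  )
}

fixture_events <- function(...) dplyr::bind_rows(...)

# one-deployment site at the study latitude
fixture_site <- function(site_id = "T01", latitude = 43.1, longitude = -6.3,
                         from = "2021-01-01", to = "2021-12-31") {
  tibble::tibble(
    site_id = site_id, latitude = latitude, longitude = longitude,
    utc_offset_hours = 1,
    deploy_start = as.Date(from), deploy_end = as.Date(to)
  )
}

# native-dialect CSV text written to a temp file
write_native_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- paste(
    "site_id,timestamp_iso8601_utc,class,behavior,start_offset_s,duration_s,source,mark_height"
  )
  writeLines(c(header, rows), path)
  path
}

# the published 19 visual-marking sequences in summary form: every sequence
# contains rubbing before debarking; 18 of 19 follow debarking with rubbing
visual_marking_sequences <- function() {
  seqs <- c(
    rep(list(c("START", "rubbing", "debarking", "rubbing", "END")), 18),
    list(c("START", "rubbing", "debarking", "END"))
  )
  structure(seqs, class = "bear_sequences")
}
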