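#' @importFrom dplyr %>%
NULL

.native_cols <- c(
  "site_id", "timestamp_iso8601_utc", "class", "behavior",
  "start_offset_s", "duration_s", "source", "mark_height"
)
.boris_cols <- c("Observation id", "Subject", "Behavior", "Start (s)", "Stop (s)")

new_bout_tbl <- function(behavior = character(), start_offset_s = numeric(),
                         duration_s = numeric()) {
  tibble::tibble(
    behavior = as.character(behavior),
    start_offset_s = as.numeric(start_offset_s),
    duration_s = as.numeric(duration_s)
  )
}

empty_detections <- function() {
  tibble::tibble(
    detection_id = character(), site_id = character(),
    start = as.POSIXct(character(), tz = "UTC"), class = character(),
    source = character(), mark_height = character(), bouts = list()
  )
}

check_behaviors <- function(codes) {
  bad <- setdiff(unique(codes), .behavior_codes)
  if (length(bad) > 0) {
    stop(
      "unknown behavior code(s): ", paste(bad, collapse = ", "),
      "; allowed codes: ", paste(.behavior_codes, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(codes)
}

check_classes <- function(cls) {
  bad <- setdiff(unique(cls), .fine_classes)
  if (length(bad) > 0) {
    warning(
      "unrecognized class labels coerced to 'unknown': ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
    cls[cls %in% bad] <- "unknown"
  }
  cls
}

#' Read a behavioral event log
#'
#' Reads camera-trap behavioral records into one row per camera trigger
#' (a "detection"), with the coded behavior bouts of that trigger nested in a
#' `bouts` list-column. Two dialects are supported:
#'
#' * `native_csv`: one row per bout with columns
#'   `site_id, timestamp_iso8601_utc, class, behavior, start_offset_s,
#'   duration_s, source, mark_height`;
#' * `boris_aggregated`: an aggregated-events export
#'   (`Observation id, Subject, Behavior, Start (s), Stop (s)`) plus a
#'   `sidecar` table mapping `observation_id` to
#'   `site_id, timestamp_iso8601_utc, class, source, mark_height`.
#'
#' @param path Path to the event CSV.
#' @param dialect `"native_csv"` (default) or `"boris_aggregated"`.
#' @param sidecar For the aggregated dialect: a data frame or CSV path with the
#'   observation metadata described above.
#' @return A tibble with columns `detection_id`, `site_id`, `start`
#'   (POSIXct, UTC), `class`, `source`, `mark_height` and list-column `bouts`
#'   (tibbles with `behavior`, `start_offset_s`, `duration_s`).
#' @export
parse_event_log <- function(path, dialect = c("native_csv", "boris_aggregated"),
                            sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  if (dialect == "native_csv") parse_native_csv(path) else parse_boris(path, sidecar)
}

parse_native_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.native_cols, names(raw))
  if (length(missing) > 0) {
    stop("event log schema error: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) return(empty_detections())
  ts <- lubridate::ymd_hms(raw$timestamp_iso8601_utc, tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) {
    bad_lines <- which(is.na(ts)) + 1L # header occupies line 1
    stop("unparseable timestamp(s) at line(s): ",
      paste(utils::head(bad_lines, 10), collapse = ", "),
      call. = FALSE
    )
  }
  check_behaviors(raw$behavior)
  raw$class <- check_classes(raw$class)
  raw$start <- ts
  off <- as.numeric(raw$start_offset_s)
  dur <- as.numeric(raw$duration_s)
  if (any(is.na(off)) || any(off < 0) || any(is.na(dur)) || any(dur < 0)) {
    stop("bout offsets/durations must be non-negative numbers", call. = FALSE)
  }
  raw$start_offset_s <- off
  raw$duration_s <- dur

  det <- raw %>%
    dplyr::group_by(.data$site_id, .data$start, .data$class, .data$source) %>%
    dplyr::summarise(
      mark_height = first_non_na(.data$mark_height),
      bouts = list(new_bout_tbl(
        .data$behavior[order(.data$start_offset_s)],
        sort(.data$start_offset_s),
        .data$duration_s[order(.data$start_offset_s)]
      )),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$start, .data$site_id)
  det$detection_id <- sprintf("d%05d", seq_len(nrow(det)))
  det[, c(
    "detection_id", "site_id", "start", "class", "source",
    "mark_height", "bouts"
  )]
}

first_non_na <- function(x) {
  x <- x[!is.na(x) & x != ""]
  if (length(x) == 0) NA_character_ else x[[1]]
}

parse_boris <- function(path, sidecar) {
  if (is.null(sidecar)) {
    stop("the aggregated dialect needs a 'sidecar' observation table", call. = FALSE)
  }
  if (is.character(sidecar)) {
    sidecar <- readr::read_csv(
      sidecar,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  sidecar <- tibble::as_tibble(sidecar)
  need <- c("observation_id", "site_id", "timestamp_iso8601_utc", "class", "source")
  missing <- setdiff(need, names(sidecar))
  if (length(missing) > 0) {
    stop("sidecar schema error: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"mark_height" %in% names(sidecar)) sidecar$mark_height <- NA_character_

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(.boris_cols, names(raw))
  if (length(missing) > 0) {
    stop("event log schema error: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) return(empty_detections())
  bouts <- tibble::tibble(
    observation_id = raw[["Observation id"]],
    behavior = tolower(gsub("[ -]", "_", raw[["Behavior"]])),
    start_offset_s = as.numeric(raw[["Start (s)"]]),
    duration_s = as.numeric(raw[["Stop (s)"]]) - as.numeric(raw[["Start (s)"]])
  )
  check_behaviors(bouts$behavior)
  unknown_obs <- setdiff(bouts$observation_id, sidecar$observation_id)
  if (length(unknown_obs) > 0) {
    stop("observation(s) missing from sidecar: ",
      paste(utils::head(unknown_obs, 10), collapse = ", "),
      call. = FALSE
    )
  }
  ts <- lubridate::ymd_hms(sidecar$timestamp_iso8601_utc, tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) {
    stop("unparseable sidecar timestamp(s) for observation(s): ",
      paste(utils::head(sidecar$observation_id[is.na(ts)], 10), collapse = ", "),
      call. = FALSE
    )
  }
  sidecar$start <- ts
  sidecar$class <- check_classes(sidecar$class)
  det <- sidecar[sidecar$observation_id %in% bouts$observation_id, ]
  det$bouts <- lapply(det$observation_id, function(oid) {
    b <- bouts[bouts$observation_id == oid, ]
    b <- b[order(b$start_offset_s), ]
    new_bout_tbl(b$behavior, b$start_offset_s, b$duration_s)
  })
  det <- det %>% dplyr::arrange(.data$start, .data$site_id)
  det$detection_id <- sprintf("d%05d", seq_len(nrow(det)))
  det$mark_height <- ifelse(is.na(det$mark_height) | det$mark_height == "",
    NA_character_, det$mark_height
  )
  det[, c(
    "detection_id", "site_id", "start", "class", "source",
    "mark_height", "bouts"
  )]
}

#' Write a behavioral event log in the native CSV dialect
#'
#' One row per bout; the inverse of [parse_event_log()] for the native
#' dialect (field-for-field lossless round trip at the detection level).
#'
#' @param x A detections or events tibble with a `bouts` list-column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path) {
  long <- tidyr::unnest(
    x[, c("site_id", "start", "class", "source", "mark_height", "bouts")],
    "bouts"
  )
  out <- tibble::tibble(
    site_id = long$site_id,
    timestamp_iso8601_utc = format(long$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    class = long$class,
    behavior = long$behavior,
    start_offset_s = long$start_offset_s,
    duration_s = long$duration_s,
    source = long$source,
    mark_height = long$mark_height
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read camera-site metadata
#'
#' @param path CSV with columns `site_id, latitude, longitude,
#'   utc_offset_hours, deploy_start, deploy_end` (one row per deployment
#'   interval; intervals are closed date ranges and must not overlap within a
#'   site).
#' @return Tibble, one row per deployment.
#' @export
read_site_metadata <- function(path) {
  sites <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    utc_offset_hours = readr::col_double(),
    deploy_start = readr::col_date(),
    deploy_end = readr::col_date()
  ))
  validate_sites(sites)
}

validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  need <- c(
    "site_id", "latitude", "longitude", "utc_offset_hours",
    "deploy_start", "deploy_end"
  )
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    stop("site metadata missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180)) {
    stop("latitude/longitude out of range", call. = FALSE)
  }
  if (any(sites$deploy_end < sites$deploy_start)) {
    stop("deployment interval ends before it starts", call. = FALSE)
  }
  for (sid in unique(sites$site_id)) {
    d <- sites[sites$site_id == sid, ][order(sites$deploy_start[sites$site_id == sid]), ]
    if (nrow(d) > 1 && any(d$deploy_start[-1] <= d$deploy_end[-nrow(d)])) {
      stop("overlapping deployment intervals for site ", sid, call. = FALSE)
    }
  }
  sites
}

#' Cluster detections into independent visit events
#'
#' Detections at the same site are merged into one visit event while the gap
#' to the previous retained detection stays within `window_minutes` (the
#' conventional camera-trap independence rule; 30 min by default). Bouts of
#' merged detections are concatenated in time order, with their offsets
#' shifted by the detection's delay from the event start. The operation is
#' idempotent: re-filtering its output with the same window changes nothing.
#'
#' @param detections Output of [parse_event_log()] (or an events tibble).
#' @param window_minutes Positive independence window in minutes.
#' @return Events tibble: `event_id`, `site_id`, `start`, `class`, `source`,
#'   `mark_height`, `bouts`, `n_detections`.
#' @export
filter_independent_events <- function(detections, window_minutes = 30) {
  stopifnot(window_minutes > 0)
  det <- tibble::as_tibble(detections)
  if (nrow(det) == 0) {
    out <- empty_detections()
    names(out)[names(out) == "detection_id"] <- "event_id"
    out$n_detections <- integer()
    return(out)
  }
  out_of_order <- vapply(
    split(as.numeric(det$start), det$site_id),
    is.unsorted, logical(1)
  )
  if (any(out_of_order)) {
    warning("detections were not in time order; sorting", call. = FALSE)
  }
  det <- det[order(det$site_id, det$start), ]

  events <- list()
  for (sid in unique(det$site_id)) {
    d <- det[det$site_id == sid, ]
    open <- NULL
    last_time <- NULL
    for (i in seq_len(nrow(d))) {
      row <- d[i, ]
      if (!is.null(open) &&
        as.numeric(difftime(row$start, last_time, units = "mins")) < window_minutes) {
        # merge into the open event
        shift <- as.numeric(difftime(row$start, open$start, units = "secs"))
        b <- row$bouts[[1]]
        b$start_offset_s <- b$start_offset_s + shift
        open$bouts[[1]] <- dplyr::bind_rows(open$bouts[[1]], b)
        if (is.na(open$mark_height)) open$mark_height <- row$mark_height
        open$n_detections <- open$n_detections + 1L
      } else {
        if (!is.null(open)) events[[length(events) + 1]] <- open
        open <- row
        open$n_detections <- 1L
      }
      last_time <- row$start
    }
    if (!is.null(open)) events[[length(events) + 1]] <- open
  }
  ev <- dplyr::bind_rows(events) %>% dplyr::arrange(.data$start, .data$site_id)
  ev$event_id <- sprintf("e%04d", seq_len(nrow(ev)))
  ev$detection_id <- NULL
  ev[, c(
    "event_id", "site_id", "start", "class", "source", "mark_height",
    "bouts", "n_detections"
  )]
}

#' Recode bouts under a merged ethogram view
#'
#' Replaces base behavior codes by the supercodes of one of the ethogram's
#' merge views (e.g. dorsal/facial -> rubbing). Consecutive same-code bouts
#' are kept distinct; collapsing duplicates is the sequence extraction's job.
#'
#' @param events Events (or detections) tibble with a `bouts` list-column.
#' @param ethogram A [bear_ethogram()].
#' @param view Name of a merge view in `ethogram$merge_maps`.
#' @return The events tibble with recoded `bouts`.
#' @export
apply_merge <- function(events, ethogram = bear_ethogram(), view) {
  if (!view %in% names(ethogram$merge_maps)) {
    stop("unknown view '", view, "'; available views: ",
      paste(names(ethogram$merge_maps), collapse = ", "),
      call. = FALSE
    )
  }
  map <- ethogram$merge_maps[[view]]
  events$bouts <- lapply(events$bouts, function(b) {
    hit <- b$behavior %in% names(map)
    b$behavior[hit] <- unname(map[b$behavior[hit]])
    b
  })
  events
}

#' Per-event behavior presence flags
#'
#' @param events Events tibble.
#' @param behaviors Behavior codes to flag; defaults to every code observed.
#' @return Logical matrix-like tibble: `event_id` plus one logical column per
#'   behavior, TRUE when the event contains at least one bout of that code.
#' @export
behavior_flags <- function(events, behaviors = NULL) {
  seen <- lapply(events$bouts, function(b) unique(b$behavior))
  if (is.null(behaviors)) behaviors <- sort(unique(unlist(seen)))
  flags <- vapply(
    behaviors,
    function(bh) vapply(seen, function(s) bh %in% s, logical(1)),
    logical(nrow(events))
  )
  if (nrow(events) == 1) flags <- matrix(flags, nrow = 1, dimnames = list(NULL, behaviors))
  dplyr::bind_cols(tibble::tibble(event_id = events$event_id), tibble::as_tibble(flags))
}

#' Behavior frequencies across visit events
#'
#' For each behavior, the number of events in which it occurs and the percent
#' of all events; behaviors co-occur within events, so the percentages need
#' not sum to 100.
#'
#' @param events Events tibble (at least one event).
#' @param behaviors Codes to tabulate; defaults to codes observed.
#' @return Tibble `behavior`, `n_events`, `percent`, sorted by frequency.
#' @export
tabulate_behavior_frequencies <- function(events, behaviors = NULL) {
  if (nrow(events) == 0) stop("empty event set", call. = FALSE)
  fl <- behavior_flags(events, behaviors)
  counts <- colSums(fl[, -1, drop = FALSE])
  tibble::tibble(
    behavior = names(counts),
    n_events = as.integer(unname(counts)),
    percent = unname(100 * counts / nrow(events))
  ) %>% dplyr::arrange(dplyr::desc(.data$n_events), .data$behavior)
}

event_categories <- function(events) {
  fl <- behavior_flags(events, .behavior_codes)
  inv <- fl$investigation
  mark <- Reduce(`|`, fl[.marking_codes])
  visual <- Reduce(`|`, fl[.visual_codes])
  tibble::tibble(
    event_id = events$event_id,
    investigation = inv & !mark,
    investigation_and_marking = inv & mark,
    marking = mark & !inv,
    visual_marking = visual,
    pedal_marking = fl$pedal
  )
}

#' Sex/age class composition of behavior categories
#'
#' Cross-tabulates events into the five reporting categories
#' (investigation only, investigation-and-marking, marking only, visual
#' marking, pedal marking; the last two overlap the first three) and expresses
#' each category column as the percentage contributed by each sex/age class,
#' so every column sums to 100.
#'
#' @param events Events tibble with `class` labels.
#' @param grouping `"coarse"` (five reporting rows) or `"fine"`.
#' @return Tibble with a `class` column and one percentage column per
#'   category; attribute `n` holds per-category event counts.
#' @export
tabulate_class_behavior <- function(events, grouping = c("coarse", "fine")) {
  grouping <- match.arg(grouping)
  cats <- event_categories(events)
  cls <- if (grouping == "coarse") {
    suppressWarnings(class_to_coarse(events$class))
  } else {
    events$class
  }
  levels <- if (grouping == "coarse") .coarse_classes else .fine_classes
  cat_names <- setdiff(names(cats), "event_id")
  n_per_cat <- integer(length(cat_names))
  names(n_per_cat) <- cat_names
  out <- tibble::tibble(class = levels)
  for (cn in cat_names) {
    in_cat <- cats[[cn]]
    n_per_cat[[cn]] <- sum(in_cat)
    by_class <- vapply(levels, function(l) sum(in_cat & cls == l), integer(1))
    out[[cn]] <- if (sum(in_cat) > 0) {
      unname(100 * by_class / sum(in_cat))
    } else {
      rep(0, length(levels))
    }
  }
  attr(out, "n") <- n_per_cat
  out
}

#' Time-budget summary of behavior durations
#'
#' Per-behavior mean, SD, min and max of the total seconds spent per event.
#' A behavior absent from an event contributes 0 s, so minima of 0 indicate
#' events in which the behavior was never performed. The caller selects the
#' event subset (e.g. only events with a timed, naturally made visual mark).
#'
#' @param events Non-empty events tibble.
#' @param behaviors Codes to summarise; defaults to codes observed.
#' @return Tibble `behavior`, `mean_s`, `sd_s`, `min_s`, `max_s`, `n`.
#' @export
summarize_durations <- function(events, behaviors = NULL) {
  if (nrow(events) == 0) stop("empty event subset", call. = FALSE)
  if (is.null(behaviors)) {
    behaviors <- sort(unique(unlist(lapply(events$bouts, function(b) b$behavior))))
  }
  per_event <- vapply(behaviors, function(bh) {
    vapply(events$bouts, function(b) sum(b$duration_s[b$behavior == bh]), numeric(1))
  }, numeric(nrow(events)))
  if (nrow(events) == 1) {
    per_event <- matrix(per_event, nrow = 1, dimnames = list(NULL, behaviors))
  }
  tibble::tibble(
    behavior = behaviors,
    mean_s = unname(apply(per_event, 2, mean)),
    sd_s = unname(apply(per_event, 2, function(x) if (length(x) > 1) stats::sd(x) else 0)),
    min_s = unname(apply(per_event, 2, min)),
    max_s = unname(apply(per_event, 2, max)),
    n = nrow(events)
  ) %>% dplyr::arrange(dplyr::desc(.data$mean_s))
}

#' Tabulate heights of visual marks
#'
#' Restricted to events with an annotated mark height; reports the split
#' between marks above and below the bear's shoulder line, overall and per
#' calendar month.
#'
#' @param events Events tibble with a `mark_height` column
#'   (`"above_shoulder"` / `"below_shoulder"` / NA).
#' @return List with `n_marks`, `percent_above`, `percent_below` and a
#'   `by_month` tibble (`month`, `n_above`, `n_below`, `percent_above`).
#' @export
tabulate_mark_heights <- function(events) {
  ann <- events[!is.na(events$mark_height), ]
  if (nrow(ann) == 0) stop("no events carry a mark-height annotation", call. = FALSE)
  bad <- setdiff(unique(ann$mark_height), c("above_shoulder", "below_shoulder"))
  if (length(bad) > 0) {
    stop("unknown mark_height value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  above <- ann$mark_height == "above_shoulder"
  by_month <- ann %>%
    dplyr::mutate(month = lubridate::month(.data$start)) %>%
    dplyr::group_by(.data$month) %>%
    dplyr::summarise(
      n_above = sum(.data$mark_height == "above_shoulder"),
      n_below = sum(.data$mark_height == "below_shoulder"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(percent_above = 100 * .data$n_above / (.data$n_above + .data$n_below))
  list(
    n_marks = nrow(ann),
    percent_above = 100 * mean(above),
    percent_below = 100 * mean(!above),
    by_month = by_month
  )
}
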