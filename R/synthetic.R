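#' Default camera-site layout for the synthetic study
#'
#' Thirteen rubbing-tree cameras scattered around 43 degrees N in the western
#' Cantabrian range, each deployed for the whole study year.
#'
#' @param n Number of sites (default 13).
#' @param year Study year (default 2021).
#' @return Site metadata tibble (one deployment row per site).
#' @export
synthetic_sites <- function(n = 13, year = 2021) {
  tibble::tibble(
    site_id = sprintf("T%02d", seq_len(n)),
    latitude = 42.95 + 0.03 * (seq_len(n) - 1) %% 7,
    longitude = -6.55 + 0.06 * (seq_len(n) - 1) %% 5,
    utc_offset_hours = 1,
    deploy_start = as.Date(sprintf("%d-01-01", year)),
    deploy_end = as.Date(sprintf("%d-12-31", year))
  )
}

#' The default ground-truth behavioral chain
#'
#' A first-order chain over the merged three-state marking repertoire
#' (`pedal`, `rubbing`, `debarking`) shaped like observed adult-male marking
#' sequences: visits open with rubbing with high probability, debarking is
#' reached only from rubbing and is almost always followed by another round
#' of rubbing, and pedal marking sits at the beginning or end of a sequence.
#'
#' @return A `transition_model` with probabilities set.
#' @export
default_transition_chain <- function() {
  states <- c("START", "debarking", "pedal", "rubbing", "END")
  p <- matrix(0, 5, 5, dimnames = list(from = states, to = states))
  p["START", "rubbing"] <- 0.89
  p["START", "pedal"] <- 0.11
  p["pedal", "rubbing"] <- 0.70
  p["pedal", "END"] <- 0.30
  p["rubbing", "debarking"] <- 0.30
  p["rubbing", "pedal"] <- 0.10
  p["rubbing", "END"] <- 0.60
  p["debarking", "rubbing"] <- 0.95
  p["debarking", "END"] <- 0.05
  transition_model_from_probs(p)
}

default_repertoire <- function() {
  tibble::tibble(
    coarse = c("adult_male", "adult_female", "subadult", "cub", "unknown"),
    p_invest = c(0.75, 0.85, 0.95, 0.90, 0.80),
    p_mark = c(0.80, 0.35, 0.12, 0.05, 0.50),
    p_dorsal = c(0.85, 0.70, 0.80, 0.80, 0.75),
    p_facial = c(0.35, 0.30, 0.20, 0.20, 0.30),
    p_pedal = c(0.45, 0.05, 0.05, 0.00, 0.15)
  )
}

default_duration_model <- function() {
  tibble::tibble(
    behavior = c(
      "dorsal", "facial", "pedal", "investigation",
      "clawing", "biting", "strip_removal"
    ),
    meanlog = log(c(20, 8, 7, 9, 10, 7, 4)),
    sdlog = c(0.6, 0.7, 0.7, 0.8, 0.6, 0.6, 0.6)
  )
}

default_height_model <- function() {
  # P(mark above shoulder | month); high during the April-May marking peak
  p <- rep(0.5, 12)
  p[3] <- 0.20
  p[4] <- 0.75
  p[5] <- 0.75
  p[6] <- 0.30
  p[7] <- 0.20
  p
}

#' Configuration of the synthetic bear-visit generator
#'
#' Bundles and validates every latent parameter of the generator: the study
#' sites and year, expected independent visits per month (peaking in May and
#' near zero in the hibernation months), a diel mixture on the sun-relative
#' time scale (a major bump at sunset, a weaker one around sunrise, plus a
#' uniform floor), the sex/age class mix, per-class behavior repertoires, the
#' ground-truth marking chain, the logistic debarking model, the mating
#' window outside which no visual marking occurs, per-behavior lognormal
#' durations, and the seasonal mark-height model.
#'
#' @param seed Integer RNG seed.
#' @param sites Site metadata tibble.
#' @param year Study year.
#' @param monthly_rate Expected independent visits per month (length 12).
#' @param diel_mixture List with `weights` (named: sunset, sunrise, uniform;
#'   summing to 1), `means` and `sds` of the two bumps on the sun-time scale.
#' @param class_mix Named probabilities over the fine sex/age classes.
#' @param repertoire Per-coarse-class behavior inclusion probabilities.
#' @param chain Ground-truth `transition_model` for marking sequences.
#' @param debark_params Named logistic coefficients `intercept`, `julian`,
#'   `sun_time` for the per-event debarking probability.
#' @param mating_window Character month-day bounds `c(from, to)` of the
#'   mating season (default April 1 to June 30).
#' @param duration_model Tibble `behavior`, `meanlog`, `sdlog` (seconds).
#' @param height_model Length-12 vector of P(mark above shoulder | month).
#' @return Validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             sites = synthetic_sites(),
                             year = 2021,
                             monthly_rate = c(4, 4, 16, 40, 56, 42, 28, 22, 18, 14, 12, 4),
                             diel_mixture = list(
                               weights = c(sunset = 0.45, sunrise = 0.25, uniform = 0.30),
                               means = c(sunset = 0.5, sunrise = -0.45),
                               sds = c(sunset = 0.12, sunrise = 0.10)
                             ),
                             class_mix = c(
                               adult_male = 0.45, adult_female = 0.08,
                               unknown_adult = 0.08, female_with_cubs = 0.06,
                               subadult_male = 0.08, subadult_female = 0.06,
                               unknown_subadult = 0.05, cub = 0.04, unknown = 0.10
                             ),
                             repertoire = default_repertoire(),
                             chain = default_transition_chain(),
                             debark_params = c(intercept = 1.75, julian = -0.02, sun_time = 1.0),
                             mating_window = c("04-01", "06-30"),
                             duration_model = default_duration_model(),
                             height_model = default_height_model()) {
  cfg <- structure(
    list(
      seed = seed, sites = validate_sites(sites), year = year,
      monthly_rate = monthly_rate, diel_mixture = diel_mixture,
      class_mix = class_mix, repertoire = repertoire, chain = chain,
      debark_params = debark_params, mating_window = mating_window,
      duration_model = duration_model, height_model = height_model
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$monthly_rate) != 12 || any(cfg$monthly_rate < 0)) {
    stop("invalid field 'monthly_rate': need 12 non-negative expected counts",
      call. = FALSE
    )
  }
  w <- cfg$diel_mixture$weights
  if (abs(sum(w) - 1) > 1e-9) {
    stop("invalid field 'diel_mixture$weights': must sum to 1", call. = FALSE)
  }
  if (!all(c("sunset", "sunrise", "uniform") %in% names(w))) {
    stop("invalid field 'diel_mixture$weights': need sunset, sunrise, uniform",
      call. = FALSE
    )
  }
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) {
    stop("invalid field 'class_mix': must sum to 1", call. = FALSE)
  }
  bad_cls <- setdiff(names(cfg$class_mix), .fine_classes)
  if (length(bad_cls) > 0) {
    stop("invalid field 'class_mix': unknown class ", paste(bad_cls, collapse = ", "),
      call. = FALSE
    )
  }
  if (!inherits(cfg$chain, "transition_model") || is.null(cfg$chain$probs)) {
    stop("invalid field 'chain': need a transition_model with probabilities",
      call. = FALSE
    )
  }
  rs <- rowSums(cfg$chain$probs)
  if (any(rs > 0 & abs(rs - 1) > 1e-9)) {
    stop("invalid field 'chain': rows must be stochastic", call. = FALSE)
  }
  if (any(cfg$duration_model$sdlog <= 0)) {
    stop("invalid field 'duration_model': sdlog must be positive", call. = FALSE)
  }
  if (length(cfg$height_model) != 12 ||
    any(cfg$height_model < 0 | cfg$height_model > 1)) {
    stop("invalid field 'height_model': need 12 probabilities", call. = FALSE)
  }
  if (!all(c("intercept", "julian", "sun_time") %in% names(cfg$debark_params))) {
    stop("invalid field 'debark_params': need intercept, julian, sun_time",
      call. = FALSE
    )
  }
  cfg
}

sample_sun_time <- function(n, mixture) {
  comp <- sample(names(mixture$weights), n, replace = TRUE, prob = mixture$weights)
  u <- numeric(n)
  for (cm in c("sunset", "sunrise")) {
    idx <- comp == cm
    u[idx] <- stats::rnorm(sum(idx), mixture$means[[cm]], mixture$sds[[cm]])
  }
  u[comp == "uniform"] <- stats::runif(sum(comp == "uniform"), -1, 1)
  ((u + 1) %% 2) - 1 # wrap onto the circular [-1, 1) scale
}

sample_chain_path <- function(probs, states, max_len = 100) {
  path <- "START"
  cur <- "START"
  while (cur != "END") {
    if (length(path) >= max_len) {
      warning("sequence truncated at ", max_len, " states", call. = FALSE)
      path <- c(path, "END")
      break
    }
    cur <- sample(states, 1, prob = probs[cur, ])
    path <- c(path, cur)
  }
  path
}

#' Sample behavioral sequences from a known chain
#'
#' Used for parameter-recovery experiments: draws `n` independent
#' `START -> ... -> END` paths from a row-stochastic transition model.
#'
#' @param chain A `transition_model` with probabilities; `END` must be
#'   reachable from every transient state.
#' @param n Number of sequences.
#' @param seed Optional RNG seed (the caller's RNG state is restored).
#' @return List of `n` state vectors, class `bear_sequences`.
#' @export
generate_sequences <- function(chain, n, seed = NULL) {
  stopifnot(inherits(chain, "transition_model"), !is.null(chain$probs))
  states <- chain$states
  if (!"END" %in% states) stop("chain has no END state", call. = FALSE)
  # END must be reachable from every state with outgoing probability
  reach <- c("END")
  repeat {
    grew <- FALSE
    for (s in setdiff(states, reach)) {
      if (any(chain$probs[s, reach] > 0)) {
        reach <- c(reach, s)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  transient <- states[rowSums(chain$probs) > 0]
  if (!all(transient %in% reach)) {
    stop("END unreachable from state(s): ",
      paste(setdiff(transient, reach), collapse = ", "),
      call. = FALSE
    )
  }
  run <- function() {
    lapply(seq_len(n), function(i) sample_chain_path(chain$probs, states))
  }
  seqs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(seqs, class = "bear_sequences")
}

in_mating_window <- function(dates, window, year) {
  lo <- as.Date(paste0(year, "-", window[1]))
  hi <- as.Date(paste0(year, "-", window[2]))
  dates >= lo & dates <= hi
}

#' Generate a synthetic year of bear visits
#'
#' Draws one year of independent rubbing-tree visits with the statistical
#' structure the downstream analyses assume: monthly Poisson visit counts
#' following `monthly_rate`, visit clock times drawn from the diel mixture on
#' the sun-time scale and mapped back through the inverse sun-relative-time
#' transform of the visit's site and date, sex/age classes from `class_mix`,
#' marking sequences of adult males drawn from the ground-truth chain (with
#' debarking permitted only inside the mating window, with probability given
#' by the logistic `debark_params`), repertoire-driven behaviors for everyone
#' else, lognormal bout durations, and seasonal mark heights. Non-male and
#' out-of-window events never contain a debarking bout, by construction.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, `events.csv`,
#'   `sites.csv` and `ground_truth.json` are written there.
#' @return List with `detections` (native-schema nested tibble), `sites`,
#'   and `ground_truth` (list of every latent parameter).
#' @export
generate_events <- function(config, dir = NULL) {
  config <- validate_synthetic_config(config)
  out <- withr::with_seed(config$seed, generate_events_impl(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_event_log(out$detections, file.path(dir, "events.csv"))
    readr::write_csv(out$sites, file.path(dir, "sites.csv"))
    gt <- out$ground_truth
    gt$chain_probs <- as.data.frame(gt$chain_probs)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}

generate_events_impl <- function(config) {
  year <- config$year
  sites <- config$sites
  n_month <- stats::rpois(12, config$monthly_rate)
  rows <- list()
  site_times <- stats::setNames(
    rep(list(numeric()), nrow(sites)), sites$site_id
  )
  for (m in 1:12) {
    if (n_month[m] == 0) next
    month_start <- as.Date(sprintf("%d-%02d-01", year, m))
    ndays <- as.integer(lubridate::ceiling_date(month_start, "month") - 1 - month_start) + 1L
    for (i in seq_len(n_month[m])) {
      site <- sites[sample.int(nrow(sites), 1), ]
      # visits are independent events by definition: re-draw any time that
      # falls within the 30-min independence window of an existing visit at
      # the same site (35-min guard)
      for (try in 1:50) {
        date <- month_start + sample.int(ndays, 1) - 1L
        u <- sample_sun_time(1, config$diel_mixture)
        se <- solar_events(site$latitude, site$longitude, date)
        ts <- clock_from_sun_time(u, se$sunrise, se$sunset)
        if (length(site_times[[site$site_id]]) == 0 ||
          min(abs(site_times[[site$site_id]] - as.numeric(ts))) > 35 * 60) {
          break
        }
      }
      site_times[[site$site_id]] <- c(site_times[[site$site_id]], as.numeric(ts))
      cls <- sample(names(config$class_mix), 1, prob = config$class_mix)
      rows[[length(rows) + 1]] <- make_visit(
        config, site$site_id, date, ts, u, cls
      )
    }
  }
  det <- dplyr::bind_rows(rows) %>% dplyr::arrange(.data$start, .data$site_id)
  det$detection_id <- sprintf("d%05d", seq_len(nrow(det)))
  det <- det[, c(
    "detection_id", "site_id", "start", "class", "source",
    "mark_height", "bouts"
  )]
  list(
    detections = det,
    sites = sites,
    ground_truth = list(
      seed = config$seed, year = year,
      monthly_rate = config$monthly_rate,
      n_per_month = n_month,
      diel_mixture = config$diel_mixture,
      class_mix = as.list(config$class_mix),
      debark_params = as.list(config$debark_params),
      mating_window = config$mating_window,
      chain_states = config$chain$states,
      chain_probs = config$chain$probs
    )
  )
}

make_visit <- function(config, site_id, date, ts, sun_time, cls) {
  coarse <- suppressWarnings(class_to_coarse(cls))
  rep_row <- config$repertoire[config$repertoire$coarse == coarse, ]
  invest <- stats::runif(1) < rep_row$p_invest
  marks <- stats::runif(1) < rep_row$p_mark
  eligible <- coarse == "adult_male" &&
    in_mating_window(date, config$mating_window, config$year)

  behaviors <- character()
  debark <- FALSE
  if (marks && coarse == "adult_male") {
    # marking adult male: bout order follows the ground-truth chain
    if (eligible) {
      lp <- config$debark_params[["intercept"]] +
        config$debark_params[["julian"]] * julian_date(date) +
        config$debark_params[["sun_time"]] * sun_time
      debark <- stats::runif(1) < stats::plogis(lp)
    }
    path <- sample_conditioned_path(config$chain, want_debark = debark)
    behaviors <- map_chain_states(path, invest)
  } else if (marks) {
    behaviors <- c(
      if (invest) "investigation",
      if (stats::runif(1) < rep_row$p_dorsal) "dorsal",
      if (stats::runif(1) < rep_row$p_facial) "facial",
      if (stats::runif(1) < rep_row$p_pedal) "pedal"
    )
    if (length(behaviors) == (invest + 0)) behaviors <- c(behaviors, "dorsal")
  } else {
    behaviors <- "investigation" # plain investigation (or look-only) visit
  }

  dm <- config$duration_model
  durations <- vapply(behaviors, function(b) {
    row <- dm[dm$behavior == b, ]
    min(60, stats::rlnorm(1, row$meanlog, row$sdlog))
  }, numeric(1))
  gaps <- stats::runif(length(behaviors), 1, 5)
  offsets <- cumsum(c(0, utils::head(durations, -1) + utils::head(gaps, -1)))

  height <- NA_character_
  if (debark) {
    p_above <- config$height_model[lubridate::month(date)]
    height <- if (stats::runif(1) < p_above) "above_shoulder" else "below_shoulder"
  }
  tibble::tibble(
    site_id = site_id, start = ts, class = cls, source = "systematic",
    mark_height = height,
    bouts = list(new_bout_tbl(behaviors, offsets, durations))
  )
}

# rejection-sample a chain path conditioned on containing (or not) debarking
sample_conditioned_path <- function(chain, want_debark, max_tries = 500) {
  for (i in seq_len(max_tries)) {
    path <- sample_chain_path(chain$probs, chain$states)
    if (("debarking" %in% path) == want_debark) return(path)
  }
  stop("could not sample a chain path with debarking = ", want_debark, call. = FALSE)
}

map_chain_states <- function(path, invest) {
  core <- path[!path %in% c("START", "END")]
  out <- character()
  for (j in seq_along(core)) {
    if (invest && (j == 1 || stats::runif(1) < 0.5)) {
      out <- c(out, "investigation")
    }
    out <- c(out, switch(core[j],
      rubbing = sample(c("dorsal", "facial"), 1, prob = c(0.7, 0.3)),
      debarking = sample(c("clawing", "biting", "strip_removal"), 1,
        prob = c(0.45, 0.35, 0.20)
      ),
      pedal = "pedal"
    ))
  }
  out
}
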