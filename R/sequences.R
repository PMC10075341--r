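#' Named presets for behavioral-sequence views
#'
#' Two standard ways of looking at a marking sequence:
#'
#' * `core_marking`: dorsal/facial coupled into `rubbing`, the three visual
#'   actions coupled into `debarking`, and `investigation` dropped (it occurs
#'   at essentially every transition and would dominate the diagram), leaving
#'   the three-state repertoire `pedal` / `rubbing` / `debarking`;
#' * `five_state`: the visual actions coupled into `debarking` but dorsal,
#'   facial, pedal and investigation kept distinct.
#'
#' @return Named list of presets, each with elements `views` and `drop_states`.
#' @export
sequence_presets <- function() {
  list(
    core_marking = list(
      views = c("chemical_view", "visual_view"),
      drop_states = "investigation"
    ),
    five_state = list(views = "visual_view", drop_states = character())
  )
}

#' Extract behavioral sequences from visit events
#'
#' Orders each event's bouts in time, recodes them under the requested merge
#' views, removes dropped states, collapses consecutive duplicates (a
#' continued behavior is not a self-transition), and brackets the result with
#' the virtual `START` and `END` states.
#'
#' @param events Events tibble.
#' @param ethogram A [bear_ethogram()].
#' @param views Character vector of merge-view names to apply.
#' @param drop_states States removed before duplicate collapsing.
#' @return Named list (by `event_id`) of character state vectors, class
#'   `bear_sequences`.
#' @export
extract_sequences <- function(events, ethogram = bear_ethogram(),
                              views = c("chemical_view", "visual_view"),
                              drop_states = "investigation") {
  for (v in views) events <- apply_merge(events, ethogram, v)
  empty <- 0L
  seqs <- lapply(seq_len(nrow(events)), function(i) {
    b <- events$bouts[[i]]
    states <- b$behavior[order(b$start_offset_s)]
    states <- states[!states %in% drop_states]
    states <- collapse_runs(states)
    c("START", states, "END")
  })
  n_empty <- sum(vapply(seqs, length, integer(1)) == 2)
  if (n_empty > 0) {
    warning(n_empty, " event(s) contributed an empty [START, END] sequence",
      call. = FALSE
    )
  }
  names(seqs) <- events$event_id
  structure(seqs, class = "bear_sequences")
}

collapse_runs <- function(x) {
  if (length(x) <= 1) return(x)
  x[c(TRUE, x[-1] != x[-length(x)])]
}

#' Count first-order transitions over a set of sequences
#'
#' Adjacent state pairs are pooled over all sequences; transitions never cross
#' event boundaries. The state order is deterministic: `START`, the
#' lexicographically sorted observed states, `END`.
#'
#' @param sequences List of state vectors (see [extract_sequences()]).
#' @param states Optional explicit state order (must contain every observed
#'   state).
#' @return A `transition_model` with the count matrix filled and probabilities
#'   unset.
#' @export
count_transitions <- function(sequences, states = NULL) {
  observed <- unique(unlist(sequences))
  mid <- sort(setdiff(observed, c("START", "END")))
  if (is.null(states)) states <- c("START", mid, "END")
  if (length(setdiff(observed, states)) > 0) {
    stop("states argument omits observed state(s): ",
      paste(setdiff(observed, states), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- matrix(0, length(states), length(states),
    dimnames = list(from = states, to = states)
  )
  for (s in sequences) {
    if (length(s) < 2) next
    from <- s[-length(s)]
    to <- s[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  new_transition_model(states = states, counts = counts)
}

new_transition_model <- function(states, counts, probs = NULL,
                                 prune_threshold = NULL, pruned_edges = NULL) {
  structure(
    list(
      states = states, counts = counts, probs = probs,
      prune_threshold = prune_threshold, pruned_edges = pruned_edges
    ),
    class = "transition_model"
  )
}

#' Build a transition model directly from a probability matrix
#'
#' Used to specify ground-truth chains (e.g. for the synthetic generator).
#'
#' @param probs Square row-stochastic matrix with identical row/column names;
#'   rows that sum to 0 are treated as absorbing.
#' @return A `transition_model` with `probs` set and zero counts.
#' @export
transition_model_from_probs <- function(probs) {
  stopifnot(is.matrix(probs), nrow(probs) == ncol(probs))
  states <- rownames(probs)
  stopifnot(!is.null(states), identical(states, colnames(probs)))
  rs <- rowSums(probs)
  if (any(rs > 0 & abs(rs - 1) > 1e-9)) {
    stop("probability rows must sum to 1 (or 0 for absorbing states)", call. = FALSE)
  }
  new_transition_model(
    states = states,
    counts = matrix(0, length(states), length(states),
      dimnames = dimnames(probs)
    ),
    probs = probs
  )
}

#' Estimate transition probabilities by row normalization
#'
#' Maximum-likelihood first-order Markov estimates: each row of the count
#' matrix is divided by its total. Rows with no outgoing transitions (the
#' absorbing `END` state) are left at zero and recorded in the `absorbing`
#' attribute.
#'
#' @param model A `transition_model` with counts.
#' @return The model with `probs` filled.
#' @export
estimate_probabilities <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  rs <- rowSums(model$counts)
  probs <- model$counts
  nz <- rs > 0
  probs[nz, ] <- probs[nz, , drop = FALSE] / rs[nz]
  probs[!nz, ] <- 0
  model$probs <- probs
  attr(model, "absorbing") <- model$states[!nz]
  model
}

#' Prune low-probability transitions for display
#'
#' Transitions with estimated probability strictly below `threshold` are
#' recorded in `pruned_edges` and excluded from diagram export. The
#' probability matrix itself is untouched (no renormalization): pruning is a
#' display decision focusing the diagram on predominant transitions.
#'
#' @param model A `transition_model` with probabilities.
#' @param threshold Number in `[0, 1]`; default 0.1.
#' @return The model with `prune_threshold` and `pruned_edges` set.
#' @export
prune_transitions <- function(model, threshold = 0.1) {
  stopifnot(inherits(model, "transition_model"), !is.null(model$probs))
  stopifnot(threshold >= 0, threshold <= 1)
  idx <- which(model$probs < threshold & model$counts > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = model$states[idx[, 1]],
    to = model$states[idx[, 2]],
    prob = model$probs[idx]
  )
  edges <- edges[order(edges$from, edges$to), ]
  model$prune_threshold <- threshold
  model$pruned_edges <- edges
  model
}

#' Entry and exit behavior distributions
#'
#' The `START` row gives the probability that a visit opens with each
#' behavior; the `END` column (per state with outgoing transitions) gives the
#' probability that a state closes the visit.
#'
#' @param model A `transition_model` with probabilities.
#' @return List of two tibbles `entry` (`state`, `prob`) and `exit`
#'   (`state`, `prob`), each sorted by decreasing probability.
#' @export
entry_exit_distribution <- function(model) {
  stopifnot(inherits(model, "transition_model"), !is.null(model$probs))
  p <- model$probs
  entry <- tibble::tibble(state = model$states, prob = unname(p["START", ]))
  entry <- entry[entry$prob > 0, ]
  entry <- entry[order(-entry$prob, entry$state), ]
  exit <- tibble::tibble(state = model$states, prob = unname(p[, "END"]))
  exit <- exit[exit$prob > 0 & exit$state != "START", ]
  exit <- exit[order(-exit$prob, exit$state), ]
  if (nrow(exit) == 0) {
    warning("no state reaches END in this chain", call. = FALSE)
  }
  list(entry = entry, exit = exit)
}

#' Export a transition diagram as Graphviz DOT text
#'
#' One directed edge per unpruned observed transition, labeled with its
#' 2-decimal probability; nodes and edges are emitted in lexicographic order
#' so the output is byte-identical for identical models.
#'
#' @param model A `transition_model` with probabilities (optionally pruned).
#' @param labels Optional named character vector renaming states for display.
#' @param path Optional file to write to.
#' @return DOT text (character scalar), invisibly if `path` is given.
#' @export
export_dot <- function(model, labels = NULL, path = NULL) {
  stopifnot(inherits(model, "transition_model"), !is.null(model$probs))
  lab <- function(s) {
    if (!is.null(labels) && s %in% names(labels)) labels[[s]] else s
  }
  pruned <- model$pruned_edges
  is_pruned <- function(f, t) {
    !is.null(pruned) && nrow(pruned) > 0 && any(pruned$from == f & pruned$to == t)
  }
  states <- sort(model$states)
  lines <- c("digraph transitions {", "  rankdir=LR;")
  for (s in states) {
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", s, lab(s)))
  }
  for (f in states) {
    for (t in states) {
      if (model$counts[f, t] > 0 && !is_pruned(f, t)) {
        lines <- c(lines, sprintf(
          "  \"%s\" -> \"%s\" [label=\"%.2f\"];",
          f, t, model$probs[f, t]
        ))
      }
    }
  }
  lines <- c(lines, "}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Write transition counts and probabilities as CSV matrices
#'
#' @param model A `transition_model`.
#' @param counts_path,probs_path Output CSV paths (states as header
#'   row/column); either may be NULL to skip.
#' @return Invisibly, the model.
#' @export
write_transition_csv <- function(model, counts_path = NULL, probs_path = NULL) {
  write_mat <- function(m, path) {
    df <- as.data.frame(m)
    df <- cbind(state = rownames(m), df)
    readr::write_csv(tibble::as_tibble(df), path)
  }
  if (!is.null(counts_path)) write_mat(model$counts, counts_path)
  if (!is.null(probs_path) && !is.null(model$probs)) write_mat(model$probs, probs_path)
  invisible(model)
}

#' @export
print.transition_model <- function(x, ...) {
  cat("First-order transition model over", length(x$states), "states\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  transitions observed:", sum(x$counts), "\n")
  if (!is.null(x$prune_threshold)) {
    cat(
      "  pruned (<", x$prune_threshold, "):",
      nrow(x$pruned_edges), "edge(s)\n"
    )
  }
  if (!is.null(x$probs)) {
    cat("  probabilities:\n")
    print(round(x$probs, 3))
  }
  invisible(x)
}
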