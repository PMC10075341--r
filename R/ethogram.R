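#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Closed behavior vocabulary. "investigation" is the only non-marking code;
# clawing/biting/strip_removal leave a visible mark (visual marking).
.behavior_codes <- c(
  "dorsal", "facial", "pedal", "investigation",
  "clawing", "biting", "strip_removal"
)
.visual_codes <- c("clawing", "biting", "strip_removal")
.marking_codes <- setdiff(.behavior_codes, "investigation")

.fine_classes <- c(
  "adult_male", "adult_female", "unknown_adult", "female_with_cubs",
  "subadult_male", "subadult_female", "unknown_subadult", "cub", "unknown"
)
.coarse_classes <- c("adult_male", "adult_female", "subadult", "cub", "unknown")
.fine_to_coarse_map <- c(
  adult_male       = "adult_male",
  adult_female     = "adult_female",
  female_with_cubs = "adult_female",
  unknown_adult    = "unknown",
  subadult_male    = "subadult",
  subadult_female  = "subadult",
  unknown_subadult = "subadult",
  cub              = "cub",
  unknown          = "unknown"
)

#' Behavior codes of the rubbing-tree ethogram
#'
#' @param which One of `"all"`, `"marking"` (everything except olfactory
#'   investigation) or `"visual"` (clawing, biting, removal of bark strips).
#' @return Character vector of behavior codes.
#' @export
#' @examples
#' behavior_codes("visual")
behavior_codes <- function(which = c("all", "marking", "visual")) {
  switch(match.arg(which),
    all = .behavior_codes,
    marking = .marking_codes,
    visual = .visual_codes
  )
}

#' The bear marking ethogram and its merged views
#'
#' Defines the five-category marking ethogram used to code rubbing-tree
#' footage (dorsal rubbing, facial rubbing, pedal marking, olfactory
#' investigation, and the three visual-marking actions clawing, biting and
#' experimental bark-strip removal) together with two named merge views:
#'
#' * `chemical_view`: dorsal and facial rubbing are coupled into a single
#'   `rubbing` state (the chemical information both deposit is presumed the
#'   same);
#' * `visual_view`: clawing, biting and strip removal are coupled into a
#'   single `debarking` state (a visual mark regardless of the means).
#'
#' @return An object of class `bear_ethogram`: a list with elements
#'   `behaviors` (character vector of base codes) and `merge_maps` (named list
#'   of named character vectors mapping base code to supercode).
#' @export
#' @examples
#' eth <- bear_ethogram()
#' eth$merge_maps$chemical_view
bear_ethogram <- function() {
  eth <- structure(
    list(
      behaviors = .behavior_codes,
      merge_maps = list(
        chemical_view = c(dorsal = "rubbing", facial = "rubbing"),
        visual_view = c(
          clawing = "debarking", biting = "debarking",
          strip_removal = "debarking"
        )
      )
    ),
    class = "bear_ethogram"
  )
  validate_ethogram(eth)
  eth
}

validate_ethogram <- function(eth) {
  stopifnot(is.list(eth), !is.null(eth$behaviors), !is.null(eth$merge_maps))
  for (view in names(eth$merge_maps)) {
    map <- eth$merge_maps[[view]]
    bad <- setdiff(names(map), eth$behaviors)
    if (length(bad) > 0) {
      stop("merge view '", view, "' mentions unknown codes: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    clash <- intersect(unname(map), eth$behaviors)
    if (length(clash) > 0) {
      stop("merge view '", view, "' supercodes clash with base codes: ",
        paste(clash, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(eth)
}

#' Sex/age classes of recorded bears
#'
#' Footage is coded with nine fine labels (seven identifiable classes plus
#' `unknown_adult`-style fallbacks); reporting tables use five coarse rows.
#'
#' @param level `"fine"` or `"coarse"`.
#' @return Character vector of class labels.
#' @export
bear_classes <- function(level = c("fine", "coarse")) {
  switch(match.arg(level), fine = .fine_classes, coarse = .coarse_classes)
}

#' Map fine sex/age labels to coarse reporting classes
#'
#' The fixed total map sends `female_with_cubs` to `adult_female`, every
#' subadult label to `subadult`, and `unknown_adult` to `unknown`.
#'
#' @param fine Character vector of fine class labels; labels outside the
#'   vocabulary are mapped to `"unknown"` with a warning.
#' @return Character vector of coarse class labels, same length.
#' @export
#' @examples
#' class_to_coarse(c("subadult_female", "female_with_cubs"))
class_to_coarse <- function(fine) {
  out <- unname(.fine_to_coarse_map[as.character(fine)])
  if (anyNA(out)) {
    bad <- unique(fine[is.na(out)])
    warning(
      "unrecognized class labels mapped to 'unknown': ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
    out[is.na(out)] <- "unknown"
  }
  out
}

#' Round half away from zero
#'
#' Printed percentages in rubbing-tree reports use conventional half-up
#' rounding (e.g. 21.75 -> 21.8), not the banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(21.75, 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
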