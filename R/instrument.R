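#' Define an outcome instrument
#'
#' An instrument is a bounded score with a direction of improvement. The
#' direction fixes the sign convention for every downstream analysis: for a
#' `higher_is_worse` instrument (e.g. the DASH disability score or a pain
#' numerical rating scale) a *negative* change represents improvement, while
#' for a `higher_is_better` instrument (e.g. the Constant-Murley shoulder
#' score) improvement is a *positive* change.
#'
#' @param name Short identifier, used as the column name in cohort tables.
#' @param scale_min,scale_max Scale bounds; every stored score must lie in
#'   `[scale_min, scale_max]`.
#' @param direction `"higher_is_worse"` or `"higher_is_better"`.
#' @param resolution Minimum increment of the scale (1 for an integer NRS);
#'   `NULL` for a continuous scale.
#'
#' @return An object of class `"instrument"`.
#' @examples
#' dash <- instrument("dash", 0, 100, "higher_is_worse")
#' pain <- instrument("pain_activities", 0, 10, "higher_is_worse", resolution = 1)
#' @export
instrument <- function(name, scale_min, scale_max,
                       direction = c("higher_is_worse", "higher_is_better"),
                       resolution = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  assert_number(scale_min, "scale_min")
  assert_number(scale_max, "scale_max")
  if (scale_min >= scale_max) {
    abort("`scale_min` must be strictly less than `scale_max`.")
  }
  direction <- match.arg(direction)
  if (!is.null(resolution)) {
    assert_number(resolution, "resolution", positive = TRUE)
  }
  structure(
    list(
      name = name, scale_min = scale_min, scale_max = scale_max,
      direction = direction, resolution = resolution
    ),
    class = "instrument"
  )
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf(
    "<instrument> %s [%g, %g], %s%s\n",
    x$name, x$scale_min, x$scale_max, x$direction,
    if (is.null(x$resolution)) "" else sprintf(", resolution %g", x$resolution)
  ))
  invisible(x)
}

is_instrument <- function(x) inherits(x, "instrument")

assert_instrument <- function(x) {
  if (!is_instrument(x)) abort("expected an `instrument` object (see `instrument()`).")
  invisible(x)
}

# +1 if a higher score is a better state, -1 if worse.
direction_sign <- function(instrument) {
  if (instrument$direction == "higher_is_better") 1 else -1
}

# ROC positive-class orientation for *change* scores: improvement lowers a
# higher_is_worse score and raises a higher_is_better score.
change_positive_direction <- function(instrument) {
  if (instrument$direction == "higher_is_worse") {
    "lower_indicates_positive"
  } else {
    "higher_indicates_positive"
  }
}

# ROC orientation for *state* scores where the positive class is the
# acceptable (satisfied) state: satisfied patients sit near the optimal end.
state_positive_direction <- function(instrument) {
  if (instrument$direction == "higher_is_worse") {
    "lower_indicates_positive"
  } else {
    "higher_indicates_positive"
  }
}

#' Instruments of the humeral shaft fracture trial cohort
#'
#' The four outcome instruments used throughout the package examples: the
#' DASH score (0-100, higher is worse), the Constant-Murley score (0-100,
#' higher is better), and two 11-point pain numerical rating scales (0-10,
#' higher is worse) for pain at rest and pain on activities.
#'
#' @return A named list of [instrument()] objects.
#' @export
fracture_instruments <- function() {
  list(
    dash = instrument("dash", 0, 100, "higher_is_worse"),
    constant = instrument("constant", 0, 100, "higher_is_better"),
    pain_rest = instrument("pain_rest", 0, 10, "higher_is_worse", resolution = 1),
    pain_activities = instrument("pain_activities", 0, 10, "higher_is_worse", resolution = 1)
  )
}

#' Default follow-up schedule labels
#'
#' Five post-injury follow-up visits: 6 weeks and 3, 6, 12 and 24 months.
#'
#' @return Character vector of ordered timepoint labels.
#' @export
fracture_timepoints <- function() {
  c("6wk", "3mo", "6mo", "12mo", "24mo")
}
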