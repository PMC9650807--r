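#' Read a longitudinal anchor-outcome cohort from CSV
#'
#' The expected file is long format with one row per participant x visit and
#' header columns `participant_id`, `timepoint`, `anchor`, plus one column
#' per instrument. The anchor is the 7-level satisfaction item coded 1
#' ("Very satisfied") to 7 ("Very dissatisfied"); lower is always the better
#' state and no reverse-coded dialect is accepted. Missing cells are empty
#' (or the configured sentinel).
#'
#' @param path Path to a CSV file.
#' @param instruments Named list of [instrument()] objects; one score column
#'   per instrument must be present.
#' @param timepoints Ordered character vector of scheduled visit labels
#'   (default [fracture_timepoints()]). Labels in the file must come from this
#'   schedule; they are mapped to 0-based `timepoint_index`.
#' @param na Missing-value sentinel(s) passed to the CSV reader.
#'
#' @return A tibble of follow-up records with columns `participant_id`,
#'   `timepoint`, `timepoint_index`, `anchor`, and one numeric column per
#'   instrument. A parse report (rows read, missing cells per column) is
#'   attached as attribute `"parse_report"`.
#' @export
read_cohort <- function(path, instruments, timepoints = fracture_timepoints(),
                        na = c("", "NA")) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  purrr::walk(instruments, assert_instrument)
  raw <- readr::read_csv(path, na = na, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("participant_id", "timepoint", "anchor", vapply(instruments, `[[`, "", "name"))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort file lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }

  bad_tp <- setdiff(unique(raw$timepoint), timepoints)
  if (length(bad_tp) > 0) {
    abort(sprintf(
      "unknown timepoint label(s): %s (schedule is %s)",
      paste(bad_tp, collapse = ", "), paste(timepoints, collapse = ", ")
    ))
  }

  parse_num <- function(col, what) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("malformed %s value at data row %d: '%s'", what, bad[1], col[bad[1]]))
    }
    out
  }

  records <- tibble(
    participant_id = raw$participant_id,
    timepoint = raw$timepoint,
    timepoint_index = match(raw$timepoint, timepoints) - 1L,
    anchor = parse_num(raw$anchor, "anchor")
  )
  if (any(!is.na(records$anchor) &
          (records$anchor != round(records$anchor) |
             records$anchor < 1 | records$anchor > 7))) {
    i <- which(!is.na(records$anchor) &
                 (records$anchor != round(records$anchor) |
                    records$anchor < 1 | records$anchor > 7))[1]
    abort(sprintf(
      "anchor must be an integer 1..7; participant %s at %s has %g",
      records$participant_id[i], records$timepoint[i], records$anchor[i]
    ))
  }
  records$anchor <- as.integer(records$anchor)

  for (ins in instruments) {
    sc <- parse_num(raw[[ins$name]], ins$name)
    out_of_bounds <- which(!is.na(sc) & (sc < ins$scale_min | sc > ins$scale_max))
    if (length(out_of_bounds) > 0) {
      i <- out_of_bounds[1]
      abort(sprintf(
        "score out of bounds: participant %s, timepoint %s, instrument %s = %g (allowed [%g, %g])",
        records$participant_id[i], records$timepoint[i], ins$name, sc[i],
        ins$scale_min, ins$scale_max
      ))
    }
    records[[ins$name]] <- sc
  }

  dup <- duplicated(records[c("participant_id", "timepoint_index")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate record: participant %s, timepoint %s",
      records$participant_id[i], records$timepoint[i]
    ))
  }

  attr(records, "parse_report") <- list(
    rows_read = nrow(records),
    missing_per_column = vapply(records[needed[-2]], function(x) sum(is.na(x)), 0L),
    timepoints = timepoints
  )
  records
}

#' Write a cohort table to CSV
#'
#' Writes the long-format dialect read by [read_cohort()]; missing cells are
#' left empty.
#'
#' @param records Cohort tibble as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- dplyr::select(records, -dplyr::any_of("timepoint_index"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Build consecutive-interval change pairs
#'
#' The atom of every MID analysis: one row per participant per consecutive
#' scheduled interval where *both* endpoints have a non-missing anchor and a
#' non-missing score for the instrument. The outcome change is always the
#' later score minus the earlier score, so a negative change on a
#' higher-is-worse instrument represents improvement. A skipped visit breaks
#' the chain: no pair spans a gap.
#'
#' Two anchor dichotomies are carried on each pair:
#' `improved_any` (anchor moved at least one level toward satisfaction;
#' the improved class of the ROC and predictive methods) and
#' `improved_one` (anchor moved exactly one level; the improved class of
#' the mean-change and mean-difference methods). The complementary "not
#' better" class (anchor same or worse) is shared by all methods.
#'
#' @param records Cohort tibble (see [read_cohort()]).
#' @param instrument An [instrument()] whose score column is present.
#'
#' @return A tibble with columns `participant_id`, `t_prev`, `t_next`,
#'   `score_prev`, `score_next`, `outcome_change`, `anchor_prev`,
#'   `anchor_next`, `anchor_delta`, `improved_any`, `improved_one`.
#'   Counts of candidate and excluded intervals are attached as attribute
#'   `"pair_log"`.
#' @examples
#' recs <- generate_cohort(cohort_config(n_participants = 20, seed = 1))
#' pairs <- build_change_pairs(recs, fracture_instruments()$dash)
#' @export
build_change_pairs <- function(records, instrument) {
  assert_instrument(instrument)
  score_col <- instrument$name
  if (!score_col %in% names(records)) {
    abort(sprintf("records have no column '%s'", score_col))
  }

  df <- records |>
    dplyr::select(dplyr::all_of(c("participant_id", "timepoint_index", "anchor", score_col))) |>
    dplyr::arrange(.data$participant_id, .data$timepoint_index)

  pairs <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      t_prev = dplyr::lag(.data$timepoint_index),
      score_prev = dplyr::lag(.data[[score_col]]),
      anchor_prev = dplyr::lag(.data$anchor)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t_prev), .data$timepoint_index == .data$t_prev + 1L)

  n_candidate <- nrow(pairs)
  pairs <- pairs |>
    dplyr::filter(
      !is.na(.data$anchor_prev), !is.na(.data$anchor),
      !is.na(.data$score_prev), !is.na(.data[[score_col]])
    )
  n_excluded <- n_candidate - nrow(pairs)

  out <- tibble(
    participant_id = pairs$participant_id,
    t_prev = as.integer(pairs$t_prev),
    t_next = as.integer(pairs$timepoint_index),
    score_prev = pairs$score_prev,
    score_next = pairs[[score_col]],
    outcome_change = pairs[[score_col]] - pairs$score_prev,
    anchor_prev = as.integer(pairs$anchor_prev),
    anchor_next = as.integer(pairs$anchor),
    anchor_delta = as.integer(pairs$anchor) - as.integer(pairs$anchor_prev)
  )
  out$improved_any <- out$anchor_delta <= -1L
  out$improved_one <- out$anchor_delta == -1L

  attr(out, "pair_log") <- list(
    instrument = instrument$name,
    consecutive_intervals = n_candidate,
    excluded_incomplete = n_excluded,
    pairs = nrow(out),
    n_improved_any = sum(out$improved_any),
    n_improved_one = sum(out$improved_one),
    n_not_improved = sum(!out$improved_any)
  )
  out
}

#' Dichotomize the satisfaction anchor into the acceptable symptom state
#'
#' Levels 1 ("Very satisfied") and 2 ("Satisfied") count as having reached
#' the acceptable state; levels 3 ("Somewhat satisfied") through 7 ("Very
#' dissatisfied") do not.
#'
#' @param anchor Integer vector of anchor levels (1-7), `NA` allowed.
#' @param satisfied_max_level Highest level still counted as satisfied
#'   (default 2).
#' @return Logical vector; `NA` where the anchor is missing (the record is
#'   non-evaluable and callers must exclude it).
#' @export
dichotomize_pass <- function(anchor, satisfied_max_level = 2L) {
  assert_count(satisfied_max_level, "satisfied_max_level", min = 1L)
  if (!is.numeric(anchor)) abort("`anchor` must be numeric (levels 1..7).")
  ok <- is.na(anchor) | (anchor == round(anchor) & anchor >= 1 & anchor <= 7)
  if (!all(ok)) abort("anchor levels must be integers in 1..7.")
  anchor <= satisfied_max_level
}
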