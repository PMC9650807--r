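# PASS estimation from cross-sectional states: the ROC method against the
# satisfied / not-satisfied anchor dichotomy, and the percentile method
# among satisfied participants. Both pool all follow-up time points of the
# primary analysis; a record contributes once per time point at which both
# anchor and score are present.

pass_result <- function(instrument, method, estimate, auxiliary = list()) {
  structure(
    list(
      instrument_name = instrument$name,
      method = method,
      estimate = unname(estimate),
      auxiliary = auxiliary
    ),
    class = "pass_result"
  )
}

#' @export
print.pass_result <- function(x, ...) {
  cat(sprintf("<pass_result> %s, method = %s: PASS = %.2f\n",
              x$instrument_name, x$method, x$estimate))
  if (length(x$auxiliary) > 0) {
    aux <- vapply(x$auxiliary, function(v) paste(format(v, digits = 3), collapse = ".."), "")
    cat("  ", paste(names(aux), aux, sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy pass_result
#' @export
tidy.pass_result <- function(x, ...) {
  tibble(
    instrument = x$instrument_name,
    method = x$method,
    estimate = x$estimate,
    ci_low = x$auxiliary$cutoff_ci[1] %||% NA_real_,
    ci_high = x$auxiliary$cutoff_ci[2] %||% NA_real_,
    sensitivity = x$auxiliary$sensitivity %||% NA_real_,
    specificity = x$auxiliary$specificity %||% NA_real_,
    auc = x$auxiliary$auc %||% NA_real_,
    auc_ci_low = x$auxiliary$auc_ci[1] %||% NA_real_,
    auc_ci_high = x$auxiliary$auc_ci[2] %||% NA_real_,
    n_satisfied = x$auxiliary$n_satisfied %||% NA_integer_,
    n_not_satisfied = x$auxiliary$n_not_satisfied %||% NA_integer_
  )
}

pass_states <- function(records, instrument, satisfied_max_level) {
  if (!instrument$name %in% names(records)) {
    abort(sprintf("records have no column '%s'", instrument$name))
  }
  satisfied <- dichotomize_pass(records$anchor, satisfied_max_level)
  score <- records[[instrument$name]]
  keep <- !is.na(satisfied) & !is.na(score)
  list(score = score[keep], satisfied = satisfied[keep])
}

#' PASS by the ROC method
#'
#' Dichotomises records into satisfied ("Very satisfied"/"Satisfied" on the
#' 7-level anchor) versus not satisfied, and selects the current-score
#' cut-off discriminating the two states by the closest-to-top-left
#' criterion, exactly as for the ROC MID. Scores are the records' own
#' (post) scores pooled over all time points. Bootstrap CIs for the cut-off
#' and AUC are computed the same way as for the MID; published PASS tables
#' traditionally omit them, so treat them as an extension.
#'
#' @param records Cohort tibble (see [read_cohort()]).
#' @param instrument The [instrument()] to estimate the PASS for.
#' @param satisfied_max_level Highest anchor level counted as satisfied
#'   (default 2).
#' @inheritParams mid_roc
#' @return A `"pass_result"`; see [tidy.pass_result()].
#' @export
pass_roc <- function(records, instrument, satisfied_max_level = 2L,
                     n_boot_cutoff = 1000, n_boot_auc = 2000,
                     auc_ci_method = c("bootstrap", "delong"), seed = NULL) {
  assert_instrument(instrument)
  auc_ci_method <- match.arg(auc_ci_method)
  st <- pass_states(records, instrument, satisfied_max_level)
  pos <- st$score[st$satisfied]
  neg <- st$score[!st$satisfied]
  if (length(pos) < 2 || length(neg) < 2) {
    abort(sprintf(
      "ROC PASS needs >= 2 records per state; have %d satisfied, %d not satisfied.",
      length(pos), length(neg)
    ))
  }
  dir <- state_positive_direction(instrument)
  cut <- ctl_cutoff(pos, neg, dir)
  a <- auc_value(pos, neg, dir)
  ci <- c(NA_real_, NA_real_)
  if (n_boot_cutoff > 0) {
    ci <- as.numeric(bootstrap_cutoff_ci(
      pos, neg, dir, n_boot = n_boot_cutoff,
      seed = if (is.null(seed)) NULL else seed
    ))
  }
  aci <- c(NA_real_, NA_real_)
  if (n_boot_auc > 0 || auc_ci_method == "delong") {
    aci <- as.numeric(auc_ci(pos, neg, dir, method = auc_ci_method,
                             n_boot = max(n_boot_auc, 1L),
                             seed = if (is.null(seed)) NULL else seed + 1L))
  }
  pass_result(
    instrument, "roc",
    estimate = cut[["cutoff"]],
    auxiliary = list(
      sensitivity = cut[["sensitivity"]],
      specificity = cut[["specificity"]],
      auc = a, auc_ci = aci, cutoff_ci = ci,
      n_satisfied = length(pos), n_not_satisfied = length(neg)
    )
  )
}

#' PASS by the percentile method
#'
#' The quantile of the current score among satisfied participants chosen so
#' that 75% of satisfied participants are at or beyond the threshold: the
#' 75th percentile for a higher-is-worse instrument (DASH, pain NRS), the
#' 25th for a higher-is-better one (Constant-Murley). Quantiles use linear
#' interpolation between order statistics at index `h = q * (n - 1)`.
#'
#' @inheritParams pass_roc
#' @return A `"pass_result"` whose auxiliary slot records the percentile
#'   used and the satisfied count.
#' @export
pass_percentile <- function(records, instrument, satisfied_max_level = 2L) {
  assert_instrument(instrument)
  st <- pass_states(records, instrument, satisfied_max_level)
  x <- st$score[st$satisfied]
  if (length(x) < 4) {
    abort(sprintf("percentile PASS needs >= 4 satisfied records; have %d.", length(x)))
  }
  q <- if (instrument$direction == "higher_is_worse") 0.75 else 0.25
  est <- unname(quantile(x, q, type = 7, names = FALSE))
  pass_result(
    instrument, "percentile",
    estimate = est,
    auxiliary = list(percentile = q, n_satisfied = length(x),
                     n_not_satisfied = sum(!st$satisfied))
  )
}

#' Estimate the PASS by both methods
#'
#' @inheritParams pass_roc
#' @param methods Subset of `c("roc", "percentile")`.
#' @return A tibble, one row per method, with a `status` column.
#' @export
estimate_pass <- function(records, instrument, methods = c("roc", "percentile"),
                          satisfied_max_level = 2L, n_boot = 1000,
                          n_boot_auc = 2000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- purrr::map(methods, function(m) {
    res <- tryCatch(
      switch(m,
        roc = pass_roc(records, instrument, satisfied_max_level,
                       n_boot_cutoff = n_boot, n_boot_auc = n_boot_auc,
                       seed = seed),
        percentile = pass_percentile(records, instrument, satisfied_max_level)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble(
        instrument = instrument$name, method = m, estimate = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_,
        auc_ci_low = NA_real_, auc_ci_high = NA_real_,
        n_satisfied = NA_integer_, n_not_satisfied = NA_integer_,
        status = paste("error:", conditionMessage(res))
      )
    } else {
      dplyr::mutate(tidy(res), status = "ok")
    }
  })
  dplyr::bind_rows(rows)
}

#' Plot the score distributions behind a PASS estimate
#'
#' @param object A `"pass_result"`.
#' @param records The cohort tibble the estimate was computed from.
#' @param satisfied_max_level Anchor cut used for the satisfied state.
#' @param ... Ignored.
#' @return A ggplot of score densities by satisfaction state with the PASS
#'   threshold marked.
#' @method autoplot pass_result
#' @export
autoplot.pass_result <- function(object, records, satisfied_max_level = 2L, ...) {
  inst_col <- object$instrument_name
  satisfied <- dichotomize_pass(records$anchor, satisfied_max_level)
  df <- tibble(
    score = records[[inst_col]],
    state = ifelse(satisfied, "satisfied", "not satisfied")
  )
  df <- df[!is.na(df$score) & !is.na(df$state), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$state)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = "dashed") +
    ggplot2::labs(
      x = inst_col, y = "Density", fill = NULL,
      title = sprintf("PASS (%s) = %.2f", object$method, object$estimate)
    ) +
    ggplot2::theme_minimal()
}
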