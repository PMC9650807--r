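# The four anchor-based MID estimators. Each returns a "mid_result" object
# carrying the point estimate (signed on the instrument's scale), its 95% CI,
# the group counts, and method-specific diagnostics; tidy() flattens results
# to a one-row tibble so methods stack into report tables.

mid_result <- function(instrument, method, estimate, ci, n_improved,
                       n_not_improved, auxiliary = list(), warnings = character()) {
  structure(
    list(
      instrument_name = instrument$name,
      method = method,
      estimate = unname(estimate),
      ci = unname(ci),
      n_improved = n_improved,
      n_not_improved = n_not_improved,
      auxiliary = auxiliary,
      warnings = warnings
    ),
    class = "mid_result"
  )
}

#' @export
print.mid_result <- function(x, ...) {
  cat(sprintf(
    "<mid_result> %s, method = %s\n  MID %.2f (95%% CI %.2f to %.2f), n improved = %d, n not improved = %d\n",
    x$instrument_name, x$method, x$estimate, x$ci[1], x$ci[2],
    x$n_improved, x$n_not_improved
  ))
  if (length(x$auxiliary) > 0) {
    aux <- vapply(x$auxiliary, function(v) format(v, digits = 3), "")
    cat("  ", paste(names(aux), aux, sep = " = ", collapse = ", "), "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @method tidy mid_result
#' @export
tidy.mid_result <- function(x, ...) {
  tibble(
    instrument = x$instrument_name,
    method = x$method,
    estimate = x$estimate,
    ci_low = x$ci[1],
    ci_high = x$ci[2],
    n_improved = x$n_improved,
    n_not_improved = x$n_not_improved,
    sensitivity = x$auxiliary$sensitivity %||% NA_real_,
    specificity = x$auxiliary$specificity %||% NA_real_,
    auc = x$auxiliary$auc %||% NA_real_,
    auc_ci_low = x$auxiliary$auc_ci[1] %||% NA_real_,
    auc_ci_high = x$auxiliary$auc_ci[2] %||% NA_real_
  )
}

#' @method glance mid_result
#' @export
glance.mid_result <- function(x, ...) {
  tibble(
    instrument = x$instrument_name,
    method = x$method,
    estimate = x$estimate,
    nobs = x$n_improved + x$n_not_improved
  )
}

check_pairs <- function(pairs) {
  needed <- c("outcome_change", "improved_any", "improved_one")
  if (!all(needed %in% names(pairs))) {
    abort("`pairs` must be a change-pair table from build_change_pairs().")
  }
  pairs
}

# Warn (never error) when a MID points the wrong way for improvement:
# sampling noise can flip a weak signal and the number is still reportable.
mid_sign_warning <- function(estimate, instrument) {
  expected_neg <- instrument$direction == "higher_is_worse"
  if ((expected_neg && estimate > 0) || (!expected_neg && estimate < 0)) {
    msg <- sprintf(
      "MID estimate %.3g has the opposite sign to improvement on a %s instrument.",
      estimate, instrument$direction
    )
    warn(msg)
    msg
  } else {
    character()
  }
}

#' MID by the ROC method
#'
#' Dichotomises the anchor between "better than the previous follow-up"
#' (any improvement in the satisfaction level) and "not better" (same or
#' worse), then selects the change-score cut-off discriminating the two
#' groups by the closest-to-top-left criterion. The 95% CI of the cut-off is
#' a stratified nonparametric bootstrap percentile interval; discrimination
#' is summarised by the Mann-Whitney AUC with its own CI.
#'
#' @param pairs Change-pair tibble from [build_change_pairs()].
#' @param instrument The [instrument()] the changes belong to.
#' @param n_boot_cutoff Bootstrap replications for the cut-off CI
#'   (default 1000); 0 skips the CI (point estimate unchanged).
#' @param n_boot_auc Bootstrap resamples for the AUC CI (default 2000);
#'   0 skips it.
#' @param auc_ci_method `"bootstrap"` (default) or `"delong"`.
#' @param seed Integer seed driving both bootstraps.
#' @return A `"mid_result"`; see [tidy.mid_result()].
#' @examples
#' pairs <- generate_two_group(two_group_config(seed = 1), fracture_instruments()$dash)
#' mid_roc(pairs, fracture_instruments()$dash, n_boot_cutoff = 50, n_boot_auc = 50, seed = 2)
#' @export
mid_roc <- function(pairs, instrument, n_boot_cutoff = 1000, n_boot_auc = 2000,
                    auc_ci_method = c("bootstrap", "delong"), seed = NULL) {
  assert_instrument(instrument)
  check_pairs(pairs)
  auc_ci_method <- match.arg(auc_ci_method)
  pos <- pairs$outcome_change[pairs$improved_any]
  neg <- pairs$outcome_change[!pairs$improved_any]
  if (length(pos) < 2 || length(neg) < 2) {
    abort(sprintf(
      "ROC MID needs >= 2 pairs per group; have %d improved, %d not improved.",
      length(pos), length(neg)
    ))
  }
  dir <- change_positive_direction(instrument)
  cut <- ctl_cutoff(pos, neg, dir)
  a <- auc_value(pos, neg, dir)

  seed_cut <- if (is.null(seed)) NULL else seed
  seed_auc <- if (is.null(seed)) NULL else seed + 1L
  ci <- c(NA_real_, NA_real_)
  redrawn <- 0L
  if (n_boot_cutoff > 0) {
    ci <- bootstrap_cutoff_ci(pos, neg, dir, n_boot = n_boot_cutoff,
                              seed = seed_cut)
    redrawn <- attr(ci, "redrawn")
  }
  aci <- c(NA_real_, NA_real_)
  if (n_boot_auc > 0 || auc_ci_method == "delong") {
    aci <- auc_ci(pos, neg, dir, method = auc_ci_method,
                  n_boot = max(n_boot_auc, 1L), seed = seed_auc)
  }

  warnings <- mid_sign_warning(cut[["cutoff"]], instrument)
  mid_result(
    instrument, "roc",
    estimate = cut[["cutoff"]],
    ci = as.numeric(ci),
    n_improved = length(pos),
    n_not_improved = length(neg),
    auxiliary = list(
      sensitivity = cut[["sensitivity"]],
      specificity = cut[["specificity"]],
      auc = a,
      auc_ci = as.numeric(aci),
      redrawn_resamples = redrawn
    ),
    warnings = warnings
  )
}

#' MID by the mean change method
#'
#' The arithmetic mean outcome change among pairs whose anchor improved by
#' exactly one level, with a normal-theory t interval.
#'
#' @inheritParams mid_roc
#' @return A `"mid_result"` (`n_improved` counts one-level improvers;
#'   `n_not_improved` the same-or-worse group, reported for context).
#' @export
mid_mean_change <- function(pairs, instrument) {
  assert_instrument(instrument)
  check_pairs(pairs)
  x <- pairs$outcome_change[pairs$improved_one]
  if (length(x) < 2) {
    abort(sprintf("mean change method needs >= 2 one-level improvers; have %d.",
                  length(x)))
  }
  tt <- t.test(x)
  warnings <- mid_sign_warning(mean(x), instrument)
  mid_result(
    instrument, "mean_change",
    estimate = mean(x),
    ci = as.numeric(tt$conf.int),
    n_improved = length(x),
    n_not_improved = sum(!pairs$improved_any),
    auxiliary = list(sd_change = sd(x)),
    warnings = warnings
  )
}

#' MID by the mean difference of change method
#'
#' The difference in mean outcome change between pairs improving exactly one
#' anchor level and pairs not improving (same or worse), with a Welch
#' two-sample 95% CI.
#'
#' @inheritParams mid_roc
#' @return A `"mid_result"`.
#' @export
mid_mean_difference_of_change <- function(pairs, instrument) {
  assert_instrument(instrument)
  check_pairs(pairs)
  x1 <- pairs$outcome_change[pairs$improved_one]
  x0 <- pairs$outcome_change[!pairs$improved_any]
  if (length(x1) < 2 || length(x0) < 2) {
    abort(sprintf(
      "mean difference method needs >= 2 pairs per group; have %d one-level improvers, %d not improved.",
      length(x1), length(x0)
    ))
  }
  tt <- t.test(x1, x0, var.equal = FALSE)
  est <- mean(x1) - mean(x0)
  warnings <- mid_sign_warning(est, instrument)
  mid_result(
    instrument, "mean_difference_of_change",
    estimate = est,
    ci = as.numeric(tt$conf.int),
    n_improved = length(x1),
    n_not_improved = length(x0),
    auxiliary = list(mean_improved = mean(x1), mean_not_improved = mean(x0)),
    warnings = warnings
  )
}

# Logistic fit of improvement status on change score; errors on separation
# or non-convergence since the MLE is then useless for the cut-point.
fit_improvement_logit <- function(change, improved) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, change), as.numeric(improved), family = binomial())
  )
  coefs <- fit$coefficients
  eps <- 1e-8
  separated <- all(fit$fitted.values[improved] > 1 - eps) &&
    all(fit$fitted.values[!improved] < eps)
  if (!fit$converged || separated || any(!is.finite(coefs))) {
    abort(paste(
      "logistic model did not converge (groups may be completely separated);",
      "the predictive MID is undefined here - consider the ROC method."
    ))
  }
  coefs
}

predictive_point <- function(change, improved) {
  coefs <- unname(fit_improvement_logit(change, improved))
  p <- mean(improved)
  c(estimate = (log(p / (1 - p)) - coefs[1]) / coefs[2],
    intercept = coefs[1], slope = coefs[2], prop_improved = p)
}

#' MID by the predictive modelling method
#'
#' Fits a logistic regression of improvement status (any anchor improvement
#' vs not better) on the outcome change and returns the change score at
#' which the likelihood ratio of belonging to the improved vs not-improved
#' group equals 1:
#' `MID = (ln(p / (1 - p)) - C) / B`, where `C` and `B` are the intercept
#' and slope and `p` is the observed proportion improved. The 95% CI is a
#' nonparametric percentile bootstrap over pairs.
#'
#' @inheritParams mid_roc
#' @param n_boot Bootstrap replications for the CI (default 1000); 0 skips
#'   the CI.
#' @return A `"mid_result"` whose auxiliary slot carries the intercept,
#'   slope and proportion improved.
#' @export
mid_predictive <- function(pairs, instrument, n_boot = 1000, seed = NULL) {
  assert_instrument(instrument)
  check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 10) abort(sprintf("predictive method needs >= 10 pairs; have %d.", n))
  improved <- pairs$improved_any
  if (!any(improved) || all(improved)) {
    abort("predictive method needs both improved and not-improved pairs.")
  }
  change <- pairs$outcome_change
  pt <- predictive_point(change, improved)

  ci <- c(NA_real_, NA_real_)
  redrawn <- 0L
  if (n_boot > 0) {
    assert_count(n_boot, "n_boot", min = 1L)
    reps <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        for (try in 1:100) {
          idx <- sample.int(n, n, replace = TRUE)
          est <- tryCatch(
            predictive_point(change[idx], improved[idx])[["estimate"]],
            error = function(e) NA_real_
          )
          if (is.finite(est)) return(est)
          redrawn <<- redrawn + 1L
        }
        abort("bootstrap resamples persistently degenerate for the predictive MID.")
      }, 0)
    })
    ci <- percentile_ci(reps)
  }

  warnings <- mid_sign_warning(pt[["estimate"]], instrument)
  expected_slope_neg <- instrument$direction == "higher_is_worse"
  if ((expected_slope_neg && pt[["slope"]] > 0) ||
      (!expected_slope_neg && pt[["slope"]] < 0)) {
    msg <- "logistic slope contradicts the instrument's improvement direction."
    warn(msg)
    warnings <- c(warnings, msg)
  }
  mid_result(
    instrument, "predictive",
    estimate = pt[["estimate"]],
    ci = ci,
    n_improved = sum(improved),
    n_not_improved = sum(!improved),
    auxiliary = list(
      intercept = unname(pt[["intercept"]]),
      slope = unname(pt[["slope"]]),
      prop_improved = unname(pt[["prop_improved"]]),
      redrawn_resamples = redrawn
    ),
    warnings = warnings
  )
}

#' Estimate the MID by several methods at once
#'
#' Runs the requested estimators on one change-pair table and stacks the
#' tidied results. Estimator-level failures (e.g. too few improvers) are
#' captured in a `status` column rather than aborting the whole set.
#'
#' @inheritParams mid_roc
#' @param methods Subset of
#'   `c("roc", "mean_difference_of_change", "mean_change", "predictive")`.
#' @param n_boot Bootstrap replications for CIs (cut-off and predictive);
#'   the AUC CI uses `n_boot_auc`.
#' @return A tibble, one row per method, with a `status` column (`"ok"` or
#'   the error message).
#' @export
estimate_mid <- function(pairs, instrument,
                         methods = c("roc", "mean_difference_of_change",
                                     "mean_change", "predictive"),
                         n_boot = 1000, n_boot_auc = 2000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- purrr::imap(rlang::set_names(methods), function(m, i) {
    res <- tryCatch(
      switch(m,
        roc = mid_roc(pairs, instrument, n_boot_cutoff = n_boot,
                      n_boot_auc = n_boot_auc, seed = seed),
        mean_change = mid_mean_change(pairs, instrument),
        mean_difference_of_change = mid_mean_difference_of_change(pairs, instrument),
        predictive = mid_predictive(pairs, instrument, n_boot = n_boot, seed = seed)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble(
        instrument = instrument$name, method = m,
        estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_improved = NA_integer_, n_not_improved = NA_integer_,
        sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_,
        auc_ci_low = NA_real_, auc_ci_high = NA_real_,
        status = paste("error:", conditionMessage(res))
      )
    } else {
      dplyr::mutate(tidy(res), status = "ok")
    }
  })
  dplyr::bind_rows(rows)
}

#' Plot the change distributions behind a MID estimate
#'
#' @param object A `"mid_result"`.
#' @param pairs The change-pair tibble the estimate was computed from.
#' @param ... Ignored.
#' @return A ggplot: outcome-change densities by anchor group with the MID
#'   marked.
#' @method autoplot mid_result
#' @export
autoplot.mid_result <- function(object, pairs, ...) {
  check_pairs(pairs)
  df <- dplyr::mutate(
    pairs,
    group = ifelse(.data$improved_any, "improved", "not improved")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome_change,
                                   fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s change", object$instrument_name),
      y = "Density", fill = NULL,
      title = sprintf("MID (%s) = %.2f", object$method, object$estimate)
    ) +
    ggplot2::theme_minimal()
}
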