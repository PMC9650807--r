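# Empirical ROC machinery: curve construction over midpoint thresholds,
# Mann-Whitney AUC, DeLong and bootstrap AUC intervals, closest-to-top-left
# cut-point selection and its bootstrap interval. These carry the exact
# conventions the estimators rely on (midpoint candidate thresholds with
# infinite sentinels, deterministic tie-breaking), so they are implemented
# here rather than delegated.

match_direction <- function(positive_direction) {
  match.arg(positive_direction,
            c("lower_indicates_positive", "higher_indicates_positive"))
}

# Candidate thresholds: midpoints between consecutive distinct pooled values
# plus -Inf/+Inf sentinels. Midpoints never coincide with an observation, so
# </> classification is unambiguous even with heavy ties.
candidate_thresholds <- function(pooled) {
  v <- sort(unique(pooled))
  if (length(v) < 2) return(c(-Inf, Inf))
  c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
}

# Fast sens/spec at each threshold via counts of observations below t.
roc_table <- function(scores_pos, scores_neg, positive_direction) {
  thr <- candidate_thresholds(c(scores_pos, scores_neg))
  sp <- sort(scores_pos)
  sn <- sort(scores_neg)
  pos_below <- findInterval(thr, sp)
  neg_below <- findInterval(thr, sn)
  if (positive_direction == "lower_indicates_positive") {
    sens <- pos_below / length(sp)
    spec <- 1 - neg_below / length(sn)
  } else {
    sens <- 1 - pos_below / length(sp)
    spec <- neg_below / length(sn)
  }
  list(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Empirical ROC curve
#'
#' Builds the full empirical ROC curve of a continuous score against a
#' binary state. Candidate thresholds are the midpoints between consecutive
#' distinct pooled values plus sentinels below the minimum and above the
#' maximum, so the curve always contains the degenerate endpoints
#' (sensitivity, specificity) = (0, 1) and (1, 0). An observation is
#' classified positive when it lies strictly on the positive side of the
#' threshold (`<` for `lower_indicates_positive`, `>` otherwise).
#'
#' @param scores_pos,scores_neg Numeric scores of the positive and negative
#'   class; both must be non-empty.
#' @param positive_direction `"lower_indicates_positive"` if small scores
#'   indicate the positive class, else `"higher_indicates_positive"`.
#' @return A tibble of class `"roc_curve"` with columns `threshold`,
#'   `sensitivity`, `specificity` and attributes `n_positive`, `n_negative`,
#'   `positive_direction`.
#' @examples
#' roc_points(c(-10, -8), c(-1, 0), "lower_indicates_positive")
#' @export
roc_points <- function(scores_pos, scores_neg,
                       positive_direction = c("lower_indicates_positive",
                                              "higher_indicates_positive")) {
  positive_direction <- match_direction(positive_direction)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("degenerate ROC: both classes must be non-empty.")
  }
  tab <- roc_table(scores_pos, scores_neg, positive_direction)
  out <- tibble(
    threshold = tab$threshold,
    sensitivity = tab$sensitivity,
    specificity = tab$specificity
  )
  attr(out, "n_positive") <- length(scores_pos)
  attr(out, "n_negative") <- length(scores_neg)
  attr(out, "positive_direction") <- positive_direction
  attr(out, "pooled_median") <- median(c(scores_pos, scores_neg))
  class(out) <- c("roc_curve", class(out))
  out
}

# Mann-Whitney AUC via midranks: ties between classes count 1/2.
auc_value <- function(scores_pos, scores_neg, positive_direction) {
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n0)
  if (positive_direction == "lower_indicates_positive") 1 - a else a
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the mean over all
#' (positive, negative) score pairs of 1 if the positive observation lies on
#' the positive side of the negative one, 1/2 if tied, 0 otherwise.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(2, 4), c(1, 3), "higher_indicates_positive") # 0.75
#' @export
roc_auc <- function(scores_pos, scores_neg,
                    positive_direction = c("lower_indicates_positive",
                                           "higher_indicates_positive")) {
  positive_direction <- match_direction(positive_direction)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  if (length(scores_pos) == 0 || length(scores_neg) == 0) {
    abort("degenerate ROC: both classes must be non-empty.")
  }
  auc_value(scores_pos, scores_neg, positive_direction)
}

# DeLong structural components. psi(x, y) = 1, 1/2, 0 as x beats/ties/loses
# to y in the positive direction.
delong_variance <- function(scores_pos, scores_neg, positive_direction) {
  if (positive_direction == "lower_indicates_positive") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  # V10_i = mean_j psi(pos_i, neg_j); computed with rank tricks, ties as 1/2
  sn <- sort(scores_neg)
  v10 <- (findInterval(scores_pos, sn, left.open = TRUE) +
            findInterval(scores_pos, sn)) / (2 * n0)
  sp <- sort(scores_pos)
  v01 <- 1 - (findInterval(scores_neg, sp, left.open = TRUE) +
                findInterval(scores_neg, sp)) / (2 * n1)
  var(v10) / n1 + var(v01) / n0
}

#' Confidence interval for the AUC
#'
#' Two constructions are offered: the asymptotic normal interval from
#' DeLong's structural-components variance estimator, and a stratified
#' nonparametric bootstrap percentile interval (resampling within each
#' class). Both are clipped to `[0, 1]`. The bootstrap with 2000 resamples
#' is the default.
#'
#' @inheritParams roc_points
#' @param method `"bootstrap"` or `"delong"`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap; required for reproducibility.
#' @param conf Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
auc_ci <- function(scores_pos, scores_neg,
                   positive_direction = c("lower_indicates_positive",
                                          "higher_indicates_positive"),
                   method = c("bootstrap", "delong"),
                   n_boot = 2000, seed = NULL, conf = 0.95) {
  positive_direction <- match_direction(positive_direction)
  method <- match.arg(method)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  if (n1 < 2 || n0 < 2) {
    abort("need >= 2 observations per class for an AUC confidence interval.")
  }
  if (method == "delong") {
    a <- auc_value(scores_pos, scores_neg, positive_direction)
    v <- delong_variance(scores_pos, scores_neg, positive_direction)
    if (!is.finite(v)) {
      abort("DeLong variance undefined for this instance; use method = 'bootstrap'.")
    }
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- a + c(-1, 1) * z * sqrt(v)
  } else {
    assert_count(n_boot, "n_boot", min = 1L)
    reps <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        auc_value(
          scores_pos[sample.int(n1, n1, replace = TRUE)],
          scores_neg[sample.int(n0, n0, replace = TRUE)],
          positive_direction
        )
      }, 0)
    })
    ci <- percentile_ci(reps, conf)
  }
  pmin(pmax(ci, 0), 1)
}

# Deterministic closest-to-top-left selection on precomputed sens/spec.
# Ties: (1) higher sensitivity, (2) threshold closest to the pooled median
# (infinite sentinels lose), (3) first in threshold order.
ctl_select <- function(threshold, sens, spec, pooled_median) {
  d <- (1 - sens)^2 + (1 - spec)^2
  eps <- 1e-12
  cand <- which(d <= min(d) + eps)
  if (length(cand) > 1) {
    cand <- cand[sens[cand] >= max(sens[cand]) - eps]
  }
  if (length(cand) > 1) {
    dist_med <- abs(threshold[cand] - pooled_median)
    dist_med[!is.finite(threshold[cand])] <- Inf
    cand <- cand[which.min(dist_med)]
  }
  cand[1]
}

# Fast path: cutoff straight from the score vectors.
ctl_cutoff <- function(scores_pos, scores_neg, positive_direction) {
  tab <- roc_table(scores_pos, scores_neg, positive_direction)
  i <- ctl_select(tab$threshold, tab$sensitivity, tab$specificity,
                  median(c(scores_pos, scores_neg)))
  c(cutoff = tab$threshold[i], sensitivity = tab$sensitivity[i],
    specificity = tab$specificity[i])
}

#' Closest-to-top-left optimal cut-point
#'
#' Selects the threshold of a [roc_points()] curve minimising the squared
#' distance to the top-left corner of ROC space,
#' `(1 - sensitivity)^2 + (1 - specificity)^2`. Ties are broken
#' deterministically: first toward higher sensitivity, then toward the
#' threshold closest to the pooled sample median (infinite sentinels lose),
#' then by threshold order.
#'
#' @param curve A `"roc_curve"` object.
#' @return One-row tibble with `cutoff`, `sensitivity`, `specificity`.
#' @export
closest_topleft <- function(curve) {
  if (!inherits(curve, "roc_curve")) abort("`curve` must be a `roc_curve`.")
  pooled_median <- attr(curve, "pooled_median")
  if (is.null(pooled_median)) {
    finite <- curve$threshold[is.finite(curve$threshold)]
    pooled_median <- if (length(finite) > 0) median(finite) else 0
  }
  i <- ctl_select(curve$threshold, curve$sensitivity, curve$specificity,
                  pooled_median)
  tibble(
    cutoff = curve$threshold[i],
    sensitivity = curve$sensitivity[i],
    specificity = curve$specificity[i]
  )
}

#' Bootstrap confidence interval for the closest-to-top-left cut-off
#'
#' Percentile 2.5/97.5 interval of the closest-to-top-left cut-off over
#' stratified nonparametric resamples (positives and negatives resampled
#' within their own class, preserving the class ratio). A resample whose
#' pooled values are all tied admits no finite threshold; such degenerate
#' resamples are redrawn and counted.
#'
#' @inheritParams roc_points
#' @param n_boot Number of bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Numeric `c(low, high)` with attribute `"redrawn"` giving the
#'   count of redrawn degenerate resamples.
#' @export
bootstrap_cutoff_ci <- function(scores_pos, scores_neg,
                                positive_direction = c("lower_indicates_positive",
                                                       "higher_indicates_positive"),
                                n_boot = 1000, seed = NULL, conf = 0.95) {
  positive_direction <- match_direction(positive_direction)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  if (n1 < 2 || n0 < 2) abort("need >= 2 observations per class.")
  assert_count(n_boot, "n_boot", min = 1L)
  redrawn <- 0L
  reps <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (try in 1:100) {
        cut <- ctl_cutoff(
          scores_pos[sample.int(n1, n1, replace = TRUE)],
          scores_neg[sample.int(n0, n0, replace = TRUE)],
          positive_direction
        )[["cutoff"]]
        if (is.finite(cut)) return(cut)
        redrawn <<- redrawn + 1L
      }
      abort("bootstrap resamples persistently degenerate (all values tied).")
    }, 0)
  })
  out <- percentile_ci(reps, conf)
  attr(out, "redrawn") <- redrawn
  out
}

#' Plot an ROC curve
#'
#' @param object A `"roc_curve"` object.
#' @param mark_closest_topleft Highlight the closest-to-top-left point.
#' @param ... Ignored.
#' @return A ggplot object in 1 - specificity vs sensitivity space.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, mark_closest_topleft = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                        y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
  if (mark_closest_topleft) {
    best <- closest_topleft(object)
    p <- p + ggplot2::geom_point(
      data = best,
      ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity),
      colour = "red", size = 2
    )
  }
  p
}
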