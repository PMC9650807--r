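# Independent brute-force oracles. These re-derive the quantities the
# package computes from first principles (direct pairwise enumeration,
# exhaustive threshold search) and must stay free of the package's own
# internals.

# Positive side of a threshold, by direction. Midpoint thresholds never
# coincide with observations, so strict comparison suffices.
oracle_positive_side <- function(x, t, direction) {
  if (direction == "lower_indicates_positive") x < t else x > t
}

oracle_thresholds <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  if (length(v) < 2) return(c(-Inf, Inf))
  c(-Inf, (v[-length(v)] + v[-1]) / 2, Inf)
}

# Sens/spec at every candidate threshold by direct evaluation.
oracle_roc <- function(pos, neg, direction) {
  thr <- oracle_thresholds(pos, neg)
  sens <- vapply(thr, function(t) mean(oracle_positive_side(pos, t, direction)), 0)
  spec <- vapply(thr, function(t) mean(!oracle_positive_side(neg, t, direction)), 0)
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

# Mann-Whitney AUC by full pairwise enumeration (ties count 1/2).
oracle_auc <- function(pos, neg, direction) {
  cmp <- outer(pos, neg, function(a, b) {
    if (direction == "lower_indicates_positive") {
      (a < b) + 0.5 * (a == b)
    } else {
      (a > b) + 0.5 * (a == b)
    }
  })
  mean(cmp)
}

# Exhaustive closest-to-top-left search, independently applying the
# documented tie-break rule: min distance, then max sensitivity, then the
# threshold nearest the pooled median (infinite sentinels last), then order.
oracle_ctl <- function(pos, neg, direction) {
  tab <- oracle_roc(pos, neg, direction)
  d <- (1 - tab$sensitivity)^2 + (1 - tab$specificity)^2
  med <- median(c(pos, neg))
  dist_med <- abs(tab$threshold - med)
  dist_med[!is.finite(tab$threshold)] <- Inf
  ord <- order(round(d, 12), -round(tab$sensitivity, 12), dist_med,
               seq_along(d))
  tab[ord[1], ]
}

# DeLong variance by direct structural-components enumeration.
oracle_delong_var <- function(pos, neg, direction) {
  psi <- function(a, b) {
    if (direction == "lower_indicates_positive") {
      (a < b) + 0.5 * (a == b)
    } else {
      (a > b) + 0.5 * (a == b)
    }
  }
  m <- outer(pos, neg, psi)
  v10 <- rowMeans(m)
  v01 <- colMeans(m)
  var(v10) / length(pos) + var(v01) / length(neg)
}

# Random two-class instance with ties (integer-ish grids) for oracle sweeps.
random_roc_instance <- function() {
  n1 <- sample(2:30, 1)
  n0 <- sample(2:30, 1)
  gen <- function(n) {
    if (runif(1) < 0.5) {
      sample(-10:10, n, replace = TRUE) # heavy ties
    } else {
      round(rnorm(n, sample(c(-3, 0, 3), 1), runif(1, 0.5, 5)), 1)
    }
  }
  list(
    pos = gen(n1), neg = gen(n0),
    direction = sample(c("lower_indicates_positive",
                         "higher_indicates_positive"), 1)
  )
}

# Minimal complete synthetic cohort for unit tests: every cell present.
tiny_records <- function() {
  tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 3),
    timepoint = rep(c("6wk", "3mo", "6mo"), 2),
    timepoint_index = rep(0:2, 2),
    anchor = c(5L, 4L, 4L, 6L, 6L, 3L),
    dash = c(46, 30, 28, 60, 55, 20)
  )
}

dash_instrument <- function() instrument("dash", 0, 100, "higher_is_worse")
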