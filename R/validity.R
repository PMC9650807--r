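# Anchor-credibility screening: Spearman correlations between the anchor
# change and outcome change / prescore / postscore, with bootstrap CIs, and
# the gate that withholds MID/PASS estimation from weakly anchored
# instruments.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with at least two
#'   distinct values.
#' @return Spearman's rho in `[-1, 1]`.
#' @examples
#' spearman_rho(1:3, c(10, 20, 30)) # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need >= 3 complete pairs.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("undefined correlation: a vector is constant.")
  }
  cor(x, y, method = "spearman")
}

#' Bootstrap percentile CI for Spearman's rho
#'
#' Percentile interval over paired nonparametric resamples. A resample in
#' which either vector degenerates to a constant has no defined rho and is
#' redrawn (counted in attribute `"redrawn"`).
#'
#' @inheritParams spearman_rho
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return `c(low, high)` with attribute `"redrawn"`.
#' @export
bootstrap_rho_ci <- function(x, y, n_boot = 1000, seed = NULL, conf = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  spearman_rho(x, y) # validates the input
  assert_count(n_boot, "n_boot", min = 1L)
  n <- length(x)
  redrawn <- 0L
  reps <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]
        yb <- y[idx]
        if (length(unique(xb)) > 1 && length(unique(yb)) > 1) {
          return(cor(xb, yb, method = "spearman"))
        }
        redrawn <<- redrawn + 1L
      }
      abort("bootstrap resamples persistently constant; rho CI unavailable.")
    }, 0)
  })
  out <- percentile_ci(reps, conf)
  attr(out, "redrawn") <- redrawn
  out
}

#' Anchor-credibility profile of an instrument
#'
#' Correlates the anchor change (`anchor_delta`; negative = improvement)
#' with the outcome change, the prescore and the postscore over the
#' change-pair table, each with a bootstrap percentile CI, and flags whether
#' the instrument is credibly anchored: `credible` is true when
#' `|rho_change| >= threshold`. Descriptive labels follow the convention
#' poor (< 0.3), moderate (0.3-0.5), good (>= 0.5). At moderate correlation
#' the gate warns rather than refuses; downstream estimates should be
#' interpreted with caution.
#'
#' @param pairs Change-pair tibble from [build_change_pairs()].
#' @param instrument The [instrument()] the pairs belong to.
#' @param threshold Minimum `|rho_change|` for credibility (default 0.3).
#' @param n_boot Bootstrap resamples per CI (default 1000); 0 skips CIs.
#' @param seed Integer seed.
#' @return A one-row tibble of class `"correlation_profile"` with rho and CI
#'   columns for change/prescore/postscore, `n_pairs`, `credible`,
#'   `strength` and `threshold_used`.
#' @export
correlation_profile <- function(pairs, instrument, threshold = 0.3,
                                n_boot = 1000, seed = NULL) {
  assert_instrument(instrument)
  check_pairs(pairs)
  if (!all(c("score_prev", "score_next", "anchor_delta") %in% names(pairs))) {
    abort("`pairs` must carry score_prev/score_next/anchor_delta columns.")
  }
  one <- function(y, offset) {
    rho <- spearman_rho(pairs$anchor_delta, y)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      ci <- as.numeric(bootstrap_rho_ci(
        pairs$anchor_delta, y, n_boot = n_boot,
        seed = if (is.null(seed)) NULL else seed + offset
      ))
    }
    c(rho = rho, low = ci[1], high = ci[2])
  }
  ch <- one(pairs$outcome_change, 0L)
  pre <- one(pairs$score_prev, 1L)
  post <- one(pairs$score_next, 2L)

  credible <- abs(ch[["rho"]]) >= threshold
  strength <- if (abs(ch[["rho"]]) < 0.3) {
    "poor"
  } else if (abs(ch[["rho"]]) < 0.5) {
    "moderate"
  } else {
    "good"
  }
  if (strength == "moderate") {
    inform(sprintf(
      "instrument '%s': anchor correlation %.2f is moderate; interpret MID/PASS with caution.",
      instrument$name, ch[["rho"]]
    ))
  }
  out <- tibble(
    instrument = instrument$name,
    rho_change = ch[["rho"]], rho_change_low = ch[["low"]], rho_change_high = ch[["high"]],
    rho_prescore = pre[["rho"]], rho_prescore_low = pre[["low"]], rho_prescore_high = pre[["high"]],
    rho_postscore = post[["rho"]], rho_postscore_low = post[["low"]], rho_postscore_high = post[["high"]],
    n_pairs = nrow(pairs),
    credible = credible,
    strength = strength,
    threshold_used = threshold
  )
  class(out) <- c("correlation_profile", class(out))
  out
}
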