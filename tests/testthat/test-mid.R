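# Small hand-built change-pair tables exercise each estimator against
# closed-form oracles before the simulation-scale checks in the acceptance
# suite.

pairs_from <- function(change, anchor_delta) {
  tibble::tibble(
    participant_id = sprintf("P%d", seq_along(change)),
    t_prev = 0L, t_next = 1L,
    score_prev = 50, score_next = 50 + change,
    outcome_change = change,
    anchor_prev = 4L,
    anchor_next = 4L + as.integer(anchor_delta),
    anchor_delta = as.integer(anchor_delta),
    improved_any = anchor_delta <= -1,
    improved_one = anchor_delta == -1
  )
}

test_that("mean change method averages one-level improvers with a t interval", {
  dash <- dash_instrument()
  p <- pairs_from(c(-10, -12, -14, -1, 0), c(-1, -1, -1, 0, 1))
  res <- mid_mean_change(p, dash)
  expect_equal(res$estimate, -12)
  expect_equal(res$n_improved, 3)

  # closed-form t interval on a 4-observation instance
  x <- c(-10, -12, -14, -8)
  p4 <- pairs_from(c(x, 0, 1), c(-1, -1, -1, -1, 0, 0))
  res4 <- mid_mean_change(p4, dash)
  want <- mean(x) + c(-1, 1) * qt(0.975, 3) * sd(x) / 2
  expect_equal(res4$ci, want)

  # two-level improvers are not the mean-change population
  p_none <- pairs_from(c(-10, -12, 0), c(-2, -2, 0))
  expect_error(mid_mean_change(p_none, dash), ">= 2 one-level improvers")
})

test_that("mean difference of change uses one-level improvers vs not-better with Welch CI", {
  dash <- dash_instrument()
  p <- pairs_from(c(-10, -12, -1, 1), c(-1, -1, 0, 1))
  res <- mid_mean_difference_of_change(p, dash)
  expect_equal(res$estimate, -11)
  expect_equal(res$n_improved, 2)
  expect_equal(res$n_not_improved, 2)

  # Welch-Satterthwaite closed form on a 4 + 4 instance
  x1 <- c(-9, -12, -15, -6)
  x0 <- c(-1, 2, 0, 3)
  p8 <- pairs_from(c(x1, x0), c(rep(-1, 4), rep(0, 4)))
  res8 <- mid_mean_difference_of_change(p8, dash)
  se <- sqrt(var(x1) / 4 + var(x0) / 4)
  df <- se^4 / ((var(x1) / 4)^2 / 3 + (var(x0) / 4)^2 / 3)
  want <- (mean(x1) - mean(x0)) + c(-1, 1) * qt(0.975, df) * se
  expect_equal(res8$ci, want)

  # anchor worseners stay in the not-better group, never dropped
  expect_equal(res$auxiliary$mean_not_improved, mean(c(-1, 1)))
})

test_that("predictive MID solves the likelihood-ratio-1 point of the logistic fit", {
  dash <- dash_instrument()
  set.seed(21)
  change <- c(rnorm(60, -10, 5), rnorm(60, 0, 5))
  delta <- c(rep(-1, 60), rep(0, 60))
  p <- pairs_from(change, delta)
  res <- mid_predictive(p, dash, n_boot = 0)
  # p = 0.5 makes ln(p/(1-p)) vanish: estimate reduces to -C/B
  expect_equal(res$estimate,
               -res$auxiliary$intercept / res$auxiliary$slope)
  # and matches an independent glm() fit
  fit <- glm(I(delta == -1) ~ change, family = binomial())
  expect_equal(res$estimate, unname(-coef(fit)[1] / coef(fit)[2]),
               tolerance = 1e-6)

  # non-0.5 proportion: full formula with the prior-odds offset
  p2 <- pairs_from(c(rnorm(40, -10, 5), rnorm(80, 0, 5)),
                   c(rep(-1, 40), rep(0, 80)))
  res2 <- mid_predictive(p2, dash, n_boot = 0)
  fit2 <- glm(improved_any ~ outcome_change, family = binomial(), data = p2)
  prop <- mean(p2$improved_any)
  want2 <- (log(prop / (1 - prop)) - coef(fit2)[1]) / coef(fit2)[2]
  expect_equal(res2$estimate, unname(want2), tolerance = 1e-6)

  # complete separation has no MLE
  sep <- pairs_from(c(-20, -19, -18, 5, 6, 7, 8, 9, 10, 11),
                    c(-1, -1, -1, 0, 0, 0, 0, 0, 0, 0))
  expect_error(mid_predictive(sep, dash, n_boot = 0), "separat|converge")
})

test_that("predictive bootstrap CI is seed-stable and brackets the estimate", {
  dash <- dash_instrument()
  set.seed(31)
  p <- pairs_from(c(rnorm(80, -10, 5), rnorm(100, 0, 5)),
                  c(rep(-1, 80), rep(0, 100)))
  r1 <- mid_predictive(p, dash, n_boot = 200, seed = 7)
  r2 <- mid_predictive(p, dash, n_boot = 200, seed = 7)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$estimate)
  expect_gte(r1$ci[2], r1$estimate)
})

test_that("ROC MID dichotomises on any improvement and reports discrimination", {
  dash <- dash_instrument()
  p <- pairs_from(c(-10, -8, -1, 0), c(-1, -2, 0, 1))
  res <- mid_roc(p, dash, n_boot_cutoff = 0, n_boot_auc = 0)
  expect_gt(res$estimate, -8)
  expect_lt(res$estimate, -1)
  expect_equal(res$auxiliary$sensitivity, 1)
  expect_equal(res$auxiliary$specificity, 1)
  expect_equal(res$auxiliary$auc, 1)
  expect_equal(res$n_improved, 2)

  expect_error(mid_roc(pairs_from(c(-1, 0, 1), c(-1, 0, 0)), dash),
               ">= 2 pairs per group")
})

test_that("all four estimators are affine-equivariant in the instrument scale", {
  dash <- dash_instrument()
  wide <- instrument("dash_wide", 0, 250, "higher_is_worse")
  set.seed(51)
  change <- c(rnorm(50, -12, 6), rnorm(70, -1, 6))
  delta <- c(rep(-1, 30), rep(-2, 20), rep(0, 50), rep(1, 20))
  p <- pairs_from(change, delta)
  a <- 2.5
  p_scaled <- p
  p_scaled$outcome_change <- a * p$outcome_change
  p_scaled$score_prev <- a * p$score_prev
  p_scaled$score_next <- a * p$score_next

  for (fn in list(
    function(q, ins) mid_roc(q, ins, n_boot_cutoff = 0, n_boot_auc = 0),
    function(q, ins) mid_mean_change(q, ins),
    function(q, ins) mid_mean_difference_of_change(q, ins),
    function(q, ins) mid_predictive(q, ins, n_boot = 0)
  )) {
    base <- fn(p, dash)$estimate
    scaled <- fn(p_scaled, wide)$estimate
    expect_equal(scaled, a * base, tolerance = 1e-6)
  }
})

test_that("a wrong-signed MID raises a warning, not an error", {
  dash <- dash_instrument()
  p <- pairs_from(c(5, 6, 4, -1, 0, -2), c(-1, -1, -1, 0, 0, 1))
  expect_warning(res <- mid_mean_change(p, dash), "opposite sign")
  expect_equal(res$estimate, 5)
})

test_that("tidy() and glance() flatten mid results for report tables", {
  dash <- dash_instrument()
  p <- pairs_from(c(-10, -8, -12, -1, 0, 2), c(-1, -1, -2, 0, 0, 1))
  res <- mid_roc(p, dash, n_boot_cutoff = 20, n_boot_auc = 20, seed = 3)
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$method, "roc")
  expect_equal(td$n_improved + td$n_not_improved, 6)
  expect_false(is.na(td$auc))
  gl <- glance(res)
  expect_equal(gl$nobs, 6)

  all4 <- estimate_mid(p, dash, n_boot = 0, n_boot_auc = 0)
  expect_equal(nrow(all4), 4)
  expect_setequal(all4$status[all4$method != "predictive"], "ok")
})
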