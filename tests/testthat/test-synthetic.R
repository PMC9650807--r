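test_that("cohort generation is seed-deterministic and complete without missingness", {
  cfg <- cohort_config(n_participants = 15, missing_rate = 0, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 15 * length(fracture_timepoints()))
  expect_true(all(stats::complete.cases(a)))

  # scores respect bounds and the NRS resolution
  expect_true(all(a$dash >= 0 & a$dash <= 100))
  expect_true(all(a$pain_activities == round(a$pain_activities)))
  expect_true(all(a$anchor %in% 1:7))
})

test_that("config invariants are enforced with named fields", {
  expect_error(cohort_config(missing_rate = 0.9), "missing_rate")
  expect_error(cohort_config(anchor_cutpoints = c(3, 2, 1, 4, 5, 6)),
               "anchor_cutpoints")
  expect_error(cohort_config(within_visit_sd = -1), "within_visit_sd")
  expect_error(cohort_config(recovery_mean_curve = c(46, 30)),
               "recovery_mean_curve")
  expect_error(two_group_config(n_not_improved = 0), "n_not_improved")
  expect_error(two_group_config(fraction_one_point = 0), "fraction_one_point")
})

test_that("the default cohort reproduces the documented first-visit moments", {
  cfg <- cohort_config(seed = 2024)
  recs <- generate_cohort(cfg)
  first <- recs[recs$timepoint_index == 0, ]
  expect_lt(abs(mean(first$dash, na.rm = TRUE) - 46), 3)
  expect_lt(abs(sd(first$dash, na.rm = TRUE) - 19), 4)
})

test_that("the default cohort reproduces the credibility split and improver share", {
  ins <- fracture_instruments()
  recs <- generate_cohort(cohort_config(seed = 77))
  dash_pairs <- build_change_pairs(recs, ins$dash)
  rest_pairs <- build_change_pairs(recs, ins$pain_rest)
  rho_dash <- spearman_rho(dash_pairs$anchor_delta, dash_pairs$outcome_change)
  rho_rest <- spearman_rho(rest_pairs$anchor_delta, rest_pairs$outcome_change)
  expect_gt(rho_dash, 0.4)
  expect_lt(rho_dash, 0.6)
  expect_lt(abs(rho_rest), 0.25)
  # roughly 40% of usable intervals improved, as in the pooled analysis
  expect_gt(mean(dash_pairs$improved_any), 0.3)
  expect_lt(mean(dash_pairs$improved_any), 0.55)
  # ~400 of 496 candidate intervals survive complete-case pairing
  expect_gt(nrow(dash_pairs), 350)
})

test_that("anchor-outcome correlation decreases as noise increases", {
  rho_at <- function(anchor_noise, instr_noise) {
    models <- midpass:::default_instrument_models()
    models$dash$noise_sd <- instr_noise
    cfg <- cohort_config(n_participants = 300, anchor_noise_sd = anchor_noise,
                         instrument_models = models, missing_rate = 0,
                         seed = 31)
    pairs <- build_change_pairs(generate_cohort(cfg), fracture_instruments()$dash)
    spearman_rho(pairs$anchor_delta, pairs$outcome_change)
  }
  by_anchor_noise <- c(rho_at(2, 8), rho_at(12, 8), rho_at(30, 8))
  expect_true(all(diff(by_anchor_noise) < 0))
  by_instr_noise <- c(rho_at(5, 2), rho_at(5, 15), rho_at(5, 40))
  expect_true(all(diff(by_instr_noise) < 0))
})

test_that("generated cohorts round-trip through CSV losslessly", {
  cfg <- cohort_config(n_participants = 25, seed = 8)
  recs <- generate_cohort(cfg)
  csv <- tempfile(fileext = ".csv")
  write_cohort(recs, csv)
  back <- read_cohort(csv, fracture_instruments())
  expect_equal(as.data.frame(back), as.data.frame(recs)[names(back)],
               ignore_attr = TRUE)
})

test_that("two-group generation matches its configuration", {
  dash <- fracture_instruments()$dash
  cfg <- two_group_config(n_improved = 10000, n_not_improved = 10000, seed = 3)
  pairs <- generate_two_group(cfg, dash)
  imp <- pairs$outcome_change[pairs$improved_any]
  noimp <- pairs$outcome_change[!pairs$improved_any]
  # empirical means within 3 standard errors of the configured means
  expect_lt(abs(mean(imp) - (-10)), 3 * 5 / sqrt(10000))
  expect_lt(abs(mean(noimp) - 0), 3 * 5 / sqrt(10000))
  expect_equal(length(imp), 10000)

  # all-one-point improvers when the fraction is 1
  cfg1 <- two_group_config(n_improved = 500, n_not_improved = 500,
                           fraction_one_point = 1, seed = 4)
  p1 <- generate_two_group(cfg1, dash)
  expect_equal(sum(p1$improved_any), sum(p1$improved_one))

  # anchor transitions are consistent with the dichotomy definitions
  expect_true(all(p1$anchor_delta[p1$improved_any] <= -1))
  expect_true(all(p1$anchor_delta[!p1$improved_any] >= 0))
})

test_that("true targets follow the equal-variance Gaussian closed forms", {
  cfg <- two_group_config(mu_improved = -10, mu_not_improved = 0,
                          sd_improved = 5, sd_not_improved = 5,
                          n_improved = 120, n_not_improved = 180)
  tg <- true_targets(cfg)
  expect_equal(tg$roc, -5)
  expect_equal(tg$mean_change, -10)
  expect_equal(tg$mean_difference_of_change, -10)

  # predictive target cross-checked by numerically solving C + Bx = ln(odds)
  # with the analytic logistic coefficients of the Gaussian mixture
  p <- 120 / 300
  sigma <- 5
  B <- (-10 - 0) / sigma^2
  C <- log(p / (1 - p)) + (0^2 - (-10)^2) / (2 * sigma^2)
  root <- uniroot(function(x) C + B * x - log(p / (1 - p)),
                  interval = c(-20, 10))$root
  expect_equal(tg$predictive, root, tolerance = 1e-6)

  expect_error(true_targets(two_group_config(sd_improved = 3, sd_not_improved = 5)),
               "no closed form")
})
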