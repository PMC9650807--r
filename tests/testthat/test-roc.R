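test_that("roc_points matches brute-force evaluation and carries its endpoints", {
  # perfect separation: some threshold attains (1, 1)
  curve <- roc_points(c(-10, -8), c(-1, 0), "lower_indicates_positive")
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_true(any(curve$sensitivity == 0 & curve$specificity == 1))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))

  # indistinguishable groups: sens + spec = 1 everywhere
  curve2 <- roc_points(5, 5, "lower_indicates_positive")
  expect_equal(curve2$sensitivity + curve2$specificity,
               rep(1, nrow(curve2)))

  # point-for-point against the brute-force oracle
  curve3 <- roc_points(c(2, 4), c(1, 3), "higher_indicates_positive")
  oracle <- oracle_roc(c(2, 4), c(1, 3), "higher_indicates_positive")
  expect_equal(curve3$threshold, oracle$threshold)
  expect_equal(curve3$sensitivity, oracle$sensitivity)
  expect_equal(curve3$specificity, oracle$specificity)

  # monotone along the curve as the threshold loosens
  expect_true(all(diff(curve3$sensitivity) <= 0))
  expect_true(all(diff(curve3$specificity) >= 0))

  expect_error(roc_points(numeric(0), 1:3), "degenerate")
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(2, 3), c(0, 1), "higher_indicates_positive"), 1)
  expect_equal(roc_auc(1, 1, "higher_indicates_positive"), 0.5)
  expect_equal(roc_auc(c(2, 4), c(1, 3), "higher_indicates_positive"), 0.75)

  set.seed(101)
  for (i in 1:25) {
    inst <- random_roc_instance()
    expect_equal(roc_auc(inst$pos, inst$neg, inst$direction),
                 oracle_auc(inst$pos, inst$neg, inst$direction))
  }
})

test_that("AUC obeys flip symmetry and monotone-transform invariance", {
  set.seed(202)
  for (i in 1:20) {
    inst <- random_roc_instance()
    a <- roc_auc(inst$pos, inst$neg, "higher_indicates_positive")
    b <- roc_auc(inst$neg, inst$pos, "lower_indicates_positive")
    expect_equal(a + (1 - b), 1)
    trans <- function(x) exp(x / 5) + x^3 / 100 # strictly increasing
    expect_equal(roc_auc(trans(inst$pos), trans(inst$neg), inst$direction),
                 roc_auc(inst$pos, inst$neg, inst$direction))
  }
})

test_that("DeLong variance matches direct structural-component enumeration and pROC", {
  skip_if_not_installed("pROC")
  set.seed(303)
  for (i in 1:10) {
    pos <- rnorm(sample(5:25, 1), 1)
    neg <- rnorm(sample(5:25, 1), 0)
    v <- midpass:::delong_variance(pos, neg, "higher_indicates_positive")
    expect_equal(v, oracle_delong_var(pos, neg, "higher_indicates_positive"))

    ci <- auc_ci(pos, neg, "higher_indicates_positive", method = "delong")
    pr <- suppressMessages(pROC::roc(
      response = c(rep(1, length(pos)), rep(0, length(neg))),
      predictor = c(pos, neg), direction = "<", quiet = TRUE
    ))
    pci <- as.numeric(suppressWarnings(pROC::ci.auc(pr, method = "delong")))
    expect_equal(ci[1], max(pci[1], 0), tolerance = 1e-8)
    expect_equal(ci[2], min(pci[3], 1), tolerance = 1e-8)
  }
})

test_that("bootstrap AUC CI is seed-reproducible and covers 0.5 under the null", {
  set.seed(404)
  pos <- rnorm(200)
  neg <- rnorm(200)
  ci1 <- auc_ci(pos, neg, "higher_indicates_positive", n_boot = 300, seed = 5)
  ci2 <- auc_ci(pos, neg, "higher_indicates_positive", n_boot = 300, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], 0.5)
  expect_gt(ci1[2], 0.5)

  # boundary: perfect separation pins the upper bound at 1
  ci3 <- auc_ci(1:50 + 100, 1:50, "higher_indicates_positive",
                n_boot = 100, seed = 1)
  expect_equal(ci3[2], 1)
})

test_that("closest_topleft agrees with exhaustive search, including tie-breaks", {
  curve <- roc_points(c(-10, -8), c(-1, 0), "lower_indicates_positive")
  best <- closest_topleft(curve)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 1)
  expect_gt(best$cutoff, -8)
  expect_lt(best$cutoff, -1)

  best2 <- closest_topleft(roc_points(c(-10, -8, -2), c(-3, -1, 0),
                                      "lower_indicates_positive"))
  oracle2 <- oracle_ctl(c(-10, -8, -2), c(-3, -1, 0), "lower_indicates_positive")
  expect_equal(best2$cutoff, oracle2$threshold)

  # constructed distance tie: pos {0, 2}, neg {1, 3} gives symmetric
  # operating points; the rule prefers higher sensitivity
  pos <- c(0, 2)
  neg <- c(1, 3)
  tie <- closest_topleft(roc_points(pos, neg, "lower_indicates_positive"))
  oracle_tie <- oracle_ctl(pos, neg, "lower_indicates_positive")
  expect_equal(tie$cutoff, oracle_tie$threshold)
  expect_equal(tie$sensitivity, oracle_tie$sensitivity)

  set.seed(505)
  for (i in 1:50) {
    inst <- random_roc_instance()
    got <- closest_topleft(roc_points(inst$pos, inst$neg, inst$direction))
    want <- oracle_ctl(inst$pos, inst$neg, inst$direction)
    expect_equal(got$cutoff, want$threshold)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("closest_topleft matches pROC's closest.topleft on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(606)
  for (i in 1:10) {
    pos <- rnorm(40, 1.2)
    neg <- rnorm(50)
    got <- closest_topleft(roc_points(pos, neg, "higher_indicates_positive"))
    pr <- suppressMessages(pROC::roc(
      response = c(rep(1, 40), rep(0, 50)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE
    ))
    co <- pROC::coords(pr, x = "best", best.method = "closest.topleft",
                       transpose = FALSE)
    expect_equal(got$cutoff, co$threshold, tolerance = 1e-8)
    expect_equal(got$sensitivity, co$sensitivity, tolerance = 1e-8)
    expect_equal(got$specificity, co$specificity, tolerance = 1e-8)
  }
})

test_that("bootstrap cutoff CI is deterministic under seed and degenerates to zero width", {
  pos <- rep(-10, 20)
  neg <- rep(0, 20)
  ci <- bootstrap_cutoff_ci(pos, neg, "lower_indicates_positive",
                            n_boot = 50, seed = 9)
  expect_equal(ci[1], -5)
  expect_equal(ci[2], -5)

  set.seed(707)
  pos2 <- rnorm(60, -8, 4)
  neg2 <- rnorm(80, 0, 4)
  a <- bootstrap_cutoff_ci(pos2, neg2, "lower_indicates_positive",
                           n_boot = 200, seed = 11)
  b <- bootstrap_cutoff_ci(pos2, neg2, "lower_indicates_positive",
                           n_boot = 200, seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))
  # percentile interval contains the point estimate on this instance
  point <- midpass:::ctl_cutoff(pos2, neg2, "lower_indicates_positive")[["cutoff"]]
  expect_lte(a[1], point)
  expect_gte(a[2], point)
})

test_that("the cutoff CI localises the equal-variance Gaussian midpoint", {
  set.seed(808)
  pos <- rnorm(500, -10, 5)
  neg <- rnorm(500, 0, 5)
  ci <- bootstrap_cutoff_ci(pos, neg, "lower_indicates_positive",
                            n_boot = 300, seed = 13)
  expect_lt(ci[1], -5)
  expect_gt(ci[2], -5)
})
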