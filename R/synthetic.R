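# Synthetic longitudinal anchor-outcome data in two modes: a trial-like
# cohort driven by a latent recovery trajectory (for end-to-end pipeline
# checks), and a two-group oracle mode with analytically known MID targets
# (for estimator validation). The study's raw data are not public, so the
# cohort mode is calibrated to the published summary structure: 124
# participants over five visits, a 7-level satisfaction anchor, three
# credibly anchored instruments and one weakly anchored one, mild
# missingness, and roughly 40% of consecutive intervals showing anchor
# improvement.

default_instrument_models <- function() {
  ins <- fracture_instruments()
  list(
    dash = list(instrument = ins$dash, intercept = 0, loading = 1,
                noise_sd = 8, round = FALSE),
    constant = list(instrument = ins$constant, intercept = 100, loading = -1.4,
                    noise_sd = 16, round = FALSE),
    pain_activities = list(instrument = ins$pain_activities, intercept = 0,
                           loading = 0.105, noise_sd = 1.5, round = TRUE),
    pain_rest = list(instrument = ins$pain_rest, intercept = 0.9,
                     loading = 0.02, noise_sd = 1.8, round = TRUE)
  )
}

#' Configuration of the latent-trajectory synthetic cohort
#'
#' Each participant carries a latent disability trajectory
#' `L[i, t] = recovery_mean_curve[t] + b[i] + e[i, t]` with a participant
#' random effect `b ~ N(0, between_participant_sd^2)` and visit noise
#' `e ~ N(0, within_visit_sd^2)`. The satisfaction anchor is an ordinal cut
#' of `anchor_loading * L + N(0, anchor_noise_sd^2)` at six increasing
#' cutpoints (7 levels, 1 = most satisfied). Each instrument observes
#' `intercept + loading * L` plus its own noise, optionally rounded to its
#' resolution and clipped to its bounds last. Cells are deleted completely
#' at random at `missing_rate`.
#'
#' Defaults emulate the structure of a humeral-shaft-fracture trial cohort:
#' 124 participants, five visits, a DASH-like instrument near mean 46
#' (SD 19) at the first visit, about 40% of consecutive intervals improved
#' on the anchor, anchor-change correlation near 0.5 for the DASH-like
#' instrument, and a pain-at-rest-like instrument whose tiny latent loading
#' leaves it weakly anchored (rho below 0.25).
#'
#' @param n_participants Number of participants (default 124).
#' @param timepoints Ordered visit labels (default [fracture_timepoints()]).
#' @param recovery_mean_curve Mean latent disability per visit, decreasing.
#' @param between_participant_sd,within_visit_sd Random-effect and visit
#'   noise SDs (> 0).
#' @param anchor_loading Latent-to-satisfaction loading.
#' @param anchor_noise_sd SD of the anchor's own noise; larger values
#'   weaken every anchor-outcome correlation.
#' @param anchor_cutpoints Six strictly increasing cutpoints on the
#'   satisfaction latent scale.
#' @param instrument_models Named list; each element has fields
#'   `instrument` ([instrument()]), `intercept`, `loading`, `noise_sd`,
#'   `round`.
#' @param missing_rate MCAR deletion rate per cell, in `[0, 0.5]`.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `"cohort_config"` list.
#' @export
cohort_config <- function(n_participants = 124L,
                          timepoints = fracture_timepoints(),
                          recovery_mean_curve = c(46, 30, 20, 14, 10),
                          between_participant_sd = 15,
                          within_visit_sd = 8,
                          anchor_loading = 1,
                          anchor_noise_sd = 5,
                          anchor_cutpoints = c(12, 32, 52, 72, 92, 112),
                          instrument_models = default_instrument_models(),
                          missing_rate = 0.05,
                          seed = NULL) {
  assert_count(n_participants, "n_participants", min = 2L)
  if (length(timepoints) < 2) abort("need at least two timepoints.")
  if (length(recovery_mean_curve) != length(timepoints)) {
    abort("`recovery_mean_curve` must have one value per timepoint.")
  }
  assert_number(between_participant_sd, "between_participant_sd", positive = TRUE)
  assert_number(within_visit_sd, "within_visit_sd", positive = TRUE)
  assert_number(anchor_loading, "anchor_loading")
  assert_number(anchor_noise_sd, "anchor_noise_sd", positive = TRUE)
  if (length(anchor_cutpoints) != 6 || any(diff(anchor_cutpoints) <= 0)) {
    abort("`anchor_cutpoints` must be 6 strictly increasing numbers.")
  }
  assert_number(missing_rate, "missing_rate")
  if (missing_rate < 0 || missing_rate > 0.5) {
    abort("`missing_rate` must lie in [0, 0.5].")
  }
  if (length(instrument_models) == 0 || is.null(names(instrument_models))) {
    abort("`instrument_models` must be a named list.")
  }
  for (nm in names(instrument_models)) {
    m <- instrument_models[[nm]]
    if (!all(c("instrument", "intercept", "loading", "noise_sd", "round") %in% names(m))) {
      abort(sprintf("instrument model '%s' lacks required fields.", nm))
    }
    assert_instrument(m$instrument)
    assert_number(m$noise_sd, sprintf("instrument_models$%s$noise_sd", nm),
                  positive = TRUE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      timepoints = timepoints,
      recovery_mean_curve = recovery_mean_curve,
      between_participant_sd = between_participant_sd,
      within_visit_sd = within_visit_sd,
      anchor_loading = anchor_loading,
      anchor_noise_sd = anchor_noise_sd,
      anchor_cutpoints = anchor_cutpoints,
      instrument_models = instrument_models,
      missing_rate = missing_rate,
      seed = seed
    ),
    class = "cohort_config"
  )
}

round_to_resolution <- function(x, resolution) {
  if (is.null(resolution)) x else round(x / resolution) * resolution
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a full cohort from a [cohort_config()]. Scores are rounded to the
#' instrument resolution (when the model's `round` flag is set) after noise
#' addition and clipped to the instrument bounds last.
#'
#' @param config A `"cohort_config"`.
#' @return A cohort tibble in the [read_cohort()] layout (with
#'   `timepoint_index`), carrying the config as attribute `"config"`.
#' @examples
#' recs <- generate_cohort(cohort_config(n_participants = 10, seed = 7))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must come from cohort_config().")
  }
  n <- config$n_participants
  nt <- length(config$timepoints)
  with_seed_if(config$seed, {
    b <- rnorm(n, 0, config$between_participant_sd)
    ids <- sprintf("P%03d", seq_len(n))
    grid <- tidyr::expand_grid(
      participant_id = ids,
      timepoint_index = seq_len(nt) - 1L
    )
    latent <- config$recovery_mean_curve[grid$timepoint_index + 1L] +
      b[match(grid$participant_id, ids)] +
      rnorm(nrow(grid), 0, config$within_visit_sd)

    anchor_latent <- config$anchor_loading * latent +
      rnorm(nrow(grid), 0, config$anchor_noise_sd)
    anchor <- findInterval(anchor_latent, config$anchor_cutpoints) + 1L

    records <- tibble(
      participant_id = grid$participant_id,
      timepoint = config$timepoints[grid$timepoint_index + 1L],
      timepoint_index = grid$timepoint_index,
      anchor = anchor
    )
    for (nm in names(config$instrument_models)) {
      m <- config$instrument_models[[nm]]
      sc <- m$intercept + m$loading * latent + rnorm(nrow(grid), 0, m$noise_sd)
      if (isTRUE(m$round)) {
        sc <- round_to_resolution(sc, m$instrument$resolution %||% 1)
      }
      sc <- pmin(pmax(sc, m$instrument$scale_min), m$instrument$scale_max)
      records[[m$instrument$name]] <- sc
    }

    if (config$missing_rate > 0) {
      cols <- c("anchor", names(config$instrument_models))
      for (col in cols) {
        drop <- runif(nrow(records)) < config$missing_rate
        records[[col]][drop] <- NA
      }
    }
    records
  }) -> records
  attr(records, "config") <- config
  records
}

#' Configuration of the two-group oracle generator
#'
#' Explicit improver / non-improver change distributions (Gaussian) with
#' analytically known targets for every MID estimator (see
#' [true_targets()]). Anchor transitions are synthesised to match the
#' dichotomies used by the estimators: a configured fraction of improvers
#' moves exactly one anchor level (the rest two), and non-improvers stay
#' level or worsen by one.
#'
#' @param mu_improved,sd_improved Mean and SD of the improvers' outcome
#'   change (on the instrument's scale, signed).
#' @param mu_not_improved,sd_not_improved Ditto for the not-improved group.
#' @param n_improved,n_not_improved Group sizes (>= 2).
#' @param fraction_one_point Fraction of improvers whose anchor improves
#'   exactly one level, in `(0, 1]`.
#' @param fraction_worsened Fraction of non-improvers whose anchor worsens
#'   by one level (the rest stay level).
#' @param seed Integer seed.
#' @return A `"two_group_config"` list.
#' @export
two_group_config <- function(mu_improved = -10, sd_improved = 5,
                             mu_not_improved = 0, sd_not_improved = 5,
                             n_improved = 200L, n_not_improved = 200L,
                             fraction_one_point = 0.6,
                             fraction_worsened = 0.3,
                             seed = NULL) {
  assert_number(mu_improved, "mu_improved")
  assert_number(mu_not_improved, "mu_not_improved")
  assert_number(sd_improved, "sd_improved", positive = TRUE)
  assert_number(sd_not_improved, "sd_not_improved", positive = TRUE)
  assert_count(n_improved, "n_improved", min = 2L)
  assert_count(n_not_improved, "n_not_improved", min = 2L)
  assert_number(fraction_one_point, "fraction_one_point")
  if (fraction_one_point <= 0 || fraction_one_point > 1) {
    abort("`fraction_one_point` must lie in (0, 1].")
  }
  assert_number(fraction_worsened, "fraction_worsened")
  if (fraction_worsened < 0 || fraction_worsened >= 1) {
    abort("`fraction_worsened` must lie in [0, 1).")
  }
  structure(
    list(
      mu_improved = mu_improved, sd_improved = sd_improved,
      mu_not_improved = mu_not_improved, sd_not_improved = sd_not_improved,
      n_improved = as.integer(n_improved),
      n_not_improved = as.integer(n_not_improved),
      fraction_one_point = fraction_one_point,
      fraction_worsened = fraction_worsened,
      seed = seed
    ),
    class = "two_group_config"
  )
}

#' Generate a two-group change-pair table with known targets
#'
#' @param config A [two_group_config()].
#' @param instrument The [instrument()] the changes nominally belong to
#'   (used for naming and downstream direction handling; scores are placed
#'   around mid-scale and are not bound-checked - this is an estimator
#'   harness, not a cohort simulator).
#' @return A change-pair tibble compatible with the MID estimators.
#' @export
generate_two_group <- function(config, instrument) {
  if (!inherits(config, "two_group_config")) {
    abort("`config` must come from two_group_config().")
  }
  assert_instrument(instrument)
  n1 <- config$n_improved
  n0 <- config$n_not_improved
  with_seed_if(config$seed, {
    change <- c(
      rnorm(n1, config$mu_improved, config$sd_improved),
      rnorm(n0, config$mu_not_improved, config$sd_not_improved)
    )
    one_point <- runif(n1) < config$fraction_one_point
    delta_imp <- ifelse(one_point, -1L, -2L)
    worsened <- runif(n0) < config$fraction_worsened
    delta_not <- ifelse(worsened, 1L, 0L)
    anchor_delta <- as.integer(c(delta_imp, delta_not))
    anchor_prev <- rep(4L, n1 + n0)
    anchor_next <- anchor_prev + anchor_delta

    mid_scale <- (instrument$scale_min + instrument$scale_max) / 2
    score_prev <- rep(mid_scale, n1 + n0)
    tibble(
      participant_id = sprintf("S%05d", seq_len(n1 + n0)),
      t_prev = 0L, t_next = 1L,
      score_prev = score_prev,
      score_next = score_prev + change,
      outcome_change = change,
      anchor_prev = anchor_prev,
      anchor_next = as.integer(anchor_next),
      anchor_delta = anchor_delta,
      improved_any = anchor_delta <= -1L,
      improved_one = anchor_delta == -1L
    )
  })
}

#' Analytic estimator targets of a two-group configuration
#'
#' Closed-form large-sample values of each MID estimator under the
#' equal-variance Gaussian two-group model with improver mean `mu1` and
#' non-improver mean `mu0`:
#' * `roc`: the closest-to-top-left cut-point is the density crossing,
#'   `(mu0 + mu1) / 2` (group-conditional operating characteristics do not
#'   depend on the group ratio);
#' * `predictive`: the likelihood-ratio-1 point. With true logistic
#'   coefficients `B = (mu1 - mu0) / sigma^2` and
#'   `C = ln(p/(1-p)) + (mu0^2 - mu1^2) / (2 sigma^2)`, the prior-odds term
#'   cancels and the target is again `(mu0 + mu1) / 2` at any proportion
#'   improved;
#' * `mean_change`: `mu1` (one-level improvers share the improver
#'   distribution);
#' * `mean_difference_of_change`: `mu1 - mu0`.
#'
#' @param config A [two_group_config()] with equal group SDs.
#' @return Named list `roc`, `predictive`, `mean_change`,
#'   `mean_difference_of_change`.
#' @export
true_targets <- function(config) {
  if (!inherits(config, "two_group_config")) {
    abort("`config` must come from two_group_config().")
  }
  if (config$sd_improved != config$sd_not_improved) {
    abort("no closed form: targets require equal group standard deviations.")
  }
  mu1 <- config$mu_improved
  mu0 <- config$mu_not_improved
  list(
    roc = (mu0 + mu1) / 2,
    predictive = (mu0 + mu1) / 2,
    mean_change = mu1,
    mean_difference_of_change = mu1 - mu0
  )
}
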