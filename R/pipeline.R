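# End-to-end orchestration of the clinimetric analysis: credibility screen,
# four MID methods, two PASS methods, pooled primary analysis and optional
# per-interval / per-timepoint secondary analysis, with CSV + JSON reports.

WITHHELD <- "withheld (anchor correlation below threshold)"

withheld_mid_row <- function(instrument, method) {
  tibble(
    instrument = instrument$name, method = method,
    estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    n_improved = NA_integer_, n_not_improved = NA_integer_,
    sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_,
    auc_ci_low = NA_real_, auc_ci_high = NA_real_,
    status = WITHHELD
  )
}

withheld_pass_row <- function(instrument, method) {
  tibble(
    instrument = instrument$name, method = method, estimate = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_,
    sensitivity = NA_real_, specificity = NA_real_, auc = NA_real_,
    auc_ci_low = NA_real_, auc_ci_high = NA_real_,
    n_satisfied = NA_integer_, n_not_satisfied = NA_integer_,
    status = WITHHELD
  )
}

#' Run the full MID/PASS analysis on an in-memory cohort
#'
#' Pipeline order: change-pair construction per instrument, anchor
#' credibility screen, then - for credible instruments only - the four MID
#' estimators and the two PASS estimators. Non-credible instruments keep
#' their correlation row but have every MID/PASS cell withheld (marked, not
#' silently dropped). MID is estimated for the improvement direction only.
#'
#' @param records Cohort tibble (see [read_cohort()] / [generate_cohort()]).
#' @param instruments Named list of [instrument()] objects.
#' @param satisfied_max_level Anchor level cut for the satisfied state.
#' @param credibility_threshold Minimum `|rho_change|` to estimate MID/PASS.
#' @param n_boot Bootstrap replications for cut-off / predictive / rho CIs;
#'   0 disables CIs (point estimates unchanged).
#' @param n_boot_auc Bootstrap resamples for AUC CIs; 0 disables them.
#' @param seed Integer seed; all stochastic steps draw reproducibly from it.
#' @param per_timepoint Also run the secondary analysis: MID per consecutive
#'   interval and PASS per timepoint.
#' @return An `"analysis_report"`: a list of tibbles `correlations`,
#'   `mid_roc`, `mid_other`, `pass`, optional `per_interval_mid` /
#'   `per_timepoint_pass`, plus `provenance` (parameters, seeds, pair logs).
#' @examples
#' recs <- generate_cohort(cohort_config(seed = 1))
#' rep <- analyze_cohort(recs, fracture_instruments(), n_boot = 0, n_boot_auc = 0)
#' rep$mid_roc
#' @export
analyze_cohort <- function(records, instruments,
                           satisfied_max_level = 2L,
                           credibility_threshold = 0.3,
                           n_boot = 1000, n_boot_auc = 2000,
                           seed = NULL, per_timepoint = FALSE) {
  purrr::walk(instruments, assert_instrument)
  inst_names <- vapply(instruments, `[[`, "", "name")
  if (is.null(names(instruments))) names(instruments) <- inst_names

  pair_sets <- purrr::map(instruments, ~ build_change_pairs(records, .x))
  pair_logs <- purrr::map(pair_sets, attr, "pair_log")

  seed_for <- function(i, block) {
    if (is.null(seed)) NULL else as.integer(seed + 100L * i + block)
  }

  correlations <- purrr::imap(instruments, function(ins, nm) {
    i <- match(nm, names(instruments))
    suppressMessages(correlation_profile(
      pair_sets[[nm]], ins, threshold = credibility_threshold,
      n_boot = n_boot, seed = seed_for(i, 0L)
    ))
  }) |> dplyr::bind_rows()

  credible <- rlang::set_names(correlations$credible, correlations$instrument)

  mid_for <- function(pairs, ins, i) {
    estimate_mid(pairs, ins, n_boot = n_boot, n_boot_auc = n_boot_auc,
                 seed = seed_for(i, 10L))
  }
  mid_all <- purrr::imap(instruments, function(ins, nm) {
    i <- match(nm, names(instruments))
    if (credible[[ins$name]]) {
      suppressWarnings(mid_for(pair_sets[[nm]], ins, i))
    } else {
      dplyr::bind_rows(purrr::map(
        c("roc", "mean_difference_of_change", "mean_change", "predictive"),
        ~ withheld_mid_row(ins, .x)
      ))
    }
  }) |> dplyr::bind_rows()

  pass_all <- purrr::imap(instruments, function(ins, nm) {
    i <- match(nm, names(instruments))
    if (credible[[ins$name]]) {
      estimate_pass(records, ins, satisfied_max_level = satisfied_max_level,
                    n_boot = n_boot, n_boot_auc = n_boot_auc,
                    seed = seed_for(i, 20L))
    } else {
      dplyr::bind_rows(withheld_pass_row(ins, "roc"),
                       withheld_pass_row(ins, "percentile"))
    }
  }) |> dplyr::bind_rows()

  per_interval_mid <- NULL
  per_timepoint_pass <- NULL
  if (isTRUE(per_timepoint)) {
    per_interval_mid <- purrr::imap(instruments, function(ins, nm) {
      i <- match(nm, names(instruments))
      if (!credible[[ins$name]]) return(NULL)
      pairs <- pair_sets[[nm]]
      purrr::map(sort(unique(pairs$t_prev)), function(tp) {
        sub <- dplyr::filter(pairs, .data$t_prev == tp)
        suppressWarnings(
          estimate_mid(sub, ins, n_boot = n_boot, n_boot_auc = n_boot_auc,
                       seed = seed_for(i, 30L + tp))
        ) |> dplyr::mutate(interval = sprintf("t%d->t%d", tp, tp + 1L),
                           .before = 1L)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    per_timepoint_pass <- purrr::imap(instruments, function(ins, nm) {
      i <- match(nm, names(instruments))
      if (!credible[[ins$name]]) return(NULL)
      purrr::map(sort(unique(records$timepoint_index)), function(tp) {
        sub <- dplyr::filter(records, .data$timepoint_index == tp)
        estimate_pass(sub, ins, satisfied_max_level = satisfied_max_level,
                      n_boot = n_boot, n_boot_auc = n_boot_auc,
                      seed = seed_for(i, 60L + tp)) |>
          dplyr::mutate(timepoint_index = tp, .before = 1L)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }

  if (!any(credible)) {
    warn(paste(
      "No instrument passed the anchor-credibility gate;",
      "the report contains the correlation table only."
    ))
  }

  structure(
    list(
      correlations = correlations,
      mid_roc = dplyr::filter(mid_all, .data$method == "roc"),
      mid_other = dplyr::filter(mid_all, .data$method != "roc"),
      pass = pass_all,
      per_interval_mid = per_interval_mid,
      per_timepoint_pass = per_timepoint_pass,
      provenance = list(
        n_records = nrow(records),
        satisfied_max_level = satisfied_max_level,
        credibility_threshold = credibility_threshold,
        n_boot = n_boot,
        n_boot_auc = n_boot_auc,
        seed = seed,
        per_timepoint = isTRUE(per_timepoint),
        pair_logs = pair_logs
      )
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, digits = 1, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, format = "f", digits = digits))
  cat("Anchor-outcome clinimetric analysis\n")
  cat(sprintf("  records: %d, credibility threshold |rho| >= %.2f\n\n",
              x$provenance$n_records, x$provenance$credibility_threshold))
  cat("Anchor correlations (rho of anchor change vs outcome change):\n")
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    cat(sprintf("  %-16s rho = %s (%s to %s)  [%s]%s\n",
                r$instrument, fmt(r$rho_change), fmt(r$rho_change_low),
                fmt(r$rho_change_high), r$strength,
                ifelse(r$credible, "", "  -> MID/PASS withheld")))
  }
  cat("\nMID (ROC method):\n")
  for (i in seq_len(nrow(x$mid_roc))) {
    r <- x$mid_roc[i, ]
    if (r$status == "ok") {
      cat(sprintf("  %-16s %s (%s to %s), sens %s, spec %s, AUC %s (%s to %s), N %d (%d/%d)\n",
                  r$instrument, fmt(r$estimate), fmt(r$ci_low), fmt(r$ci_high),
                  fmt(r$sensitivity), fmt(r$specificity), fmt(r$auc),
                  fmt(r$auc_ci_low), fmt(r$auc_ci_high),
                  r$n_improved + r$n_not_improved, r$n_improved, r$n_not_improved))
    } else {
      cat(sprintf("  %-16s %s\n", r$instrument, r$status))
    }
  }
  cat("\nMID (other methods):\n")
  for (i in seq_len(nrow(x$mid_other))) {
    r <- x$mid_other[i, ]
    if (r$status == "ok") {
      cat(sprintf("  %-16s %-26s %s (%s to %s)\n", r$instrument, r$method,
                  fmt(r$estimate), fmt(r$ci_low), fmt(r$ci_high)))
    } else {
      cat(sprintf("  %-16s %-26s %s\n", r$instrument, r$method, r$status))
    }
  }
  cat("\nPASS:\n")
  for (i in seq_len(nrow(x$pass))) {
    r <- x$pass[i, ]
    if (r$status == "ok") {
      cat(sprintf("  %-16s %-11s %s\n", r$instrument, r$method, fmt(r$estimate)))
    } else {
      cat(sprintf("  %-16s %-11s %s\n", r$instrument, r$method, r$status))
    }
  }
  invisible(x)
}

#' Read an analysis configuration file
#'
#' YAML with top-level keys `instruments` (name -> scale_min, scale_max,
#' direction, optional resolution), optional `timepoints`,
#' `satisfied_max_level`, `credibility_threshold`, `n_boot`, `n_boot_auc`,
#' `seed`, `per_timepoint`, `missing_sentinel`.
#'
#' @param path Path to a YAML config.
#' @return List with parsed `instruments` and analysis parameters.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$instruments)) abort("config must define `instruments`.")
  instruments <- purrr::imap(cfg$instruments, function(spec, nm) {
    instrument(
      name = nm,
      scale_min = spec$scale_min,
      scale_max = spec$scale_max,
      direction = spec$direction,
      resolution = spec$resolution
    )
  })
  list(
    instruments = instruments,
    timepoints = cfg$timepoints %||% fracture_timepoints(),
    satisfied_max_level = cfg$satisfied_max_level %||% 2L,
    credibility_threshold = cfg$credibility_threshold %||% 0.3,
    n_boot = cfg$n_boot %||% 1000L,
    n_boot_auc = cfg$n_boot_auc %||% 2000L,
    seed = cfg$seed,
    per_timepoint = isTRUE(cfg$per_timepoint),
    missing_sentinel = cfg$missing_sentinel %||% ""
  )
}

#' Run the analysis from files and write reports
#'
#' Reads the cohort CSV and the YAML config, runs [analyze_cohort()], and,
#' when `out_dir` is given, writes `correlations.csv`, `mid_roc.csv`,
#' `mid_other.csv`, `pass.csv`, a single `report.json` and a `run.log`
#' recording pair counts and exclusions. CSV/JSON numbers are written at
#' full precision; display rounding applies only to the printed summary.
#'
#' @param dataset_path Cohort CSV path.
#' @param config_path YAML config path.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param seed Overrides the config seed when non-`NULL`.
#' @param per_timepoint Overrides the config flag when non-`NULL`.
#' @return The `"analysis_report"`, invisibly when writing.
#' @export
run_analysis <- function(dataset_path, config_path, out_dir = NULL,
                         seed = NULL, per_timepoint = NULL) {
  cfg <- read_analysis_config(config_path)
  records <- read_cohort(dataset_path, cfg$instruments,
                         timepoints = cfg$timepoints,
                         na = unique(c(cfg$missing_sentinel, "", "NA")))
  report <- analyze_cohort(
    records, cfg$instruments,
    satisfied_max_level = cfg$satisfied_max_level,
    credibility_threshold = cfg$credibility_threshold,
    n_boot = cfg$n_boot, n_boot_auc = cfg$n_boot_auc,
    seed = seed %||% cfg$seed,
    per_timepoint = per_timepoint %||% cfg$per_timepoint
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}

#' Write an analysis report to disk
#'
#' @param report An `"analysis_report"`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "analysis_report")) {
    abort("`report` must be an analysis_report.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$correlations, file.path(out_dir, "correlations.csv"), na = "")
  readr::write_csv(report$mid_roc, file.path(out_dir, "mid_roc.csv"), na = "")
  readr::write_csv(report$mid_other, file.path(out_dir, "mid_other.csv"), na = "")
  readr::write_csv(report$pass, file.path(out_dir, "pass.csv"), na = "")
  if (!is.null(report$per_interval_mid)) {
    readr::write_csv(report$per_interval_mid,
                     file.path(out_dir, "mid_per_interval.csv"), na = "")
  }
  if (!is.null(report$per_timepoint_pass)) {
    readr::write_csv(report$per_timepoint_pass,
                     file.path(out_dir, "pass_per_timepoint.csv"), na = "")
  }
  json <- jsonlite::toJSON(
    list(
      correlations = report$correlations,
      mid_roc = report$mid_roc,
      mid_other = report$mid_other,
      pass = report$pass,
      per_interval_mid = report$per_interval_mid,
      per_timepoint_pass = report$per_timepoint_pass,
      provenance = report$provenance
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE
  )
  writeLines(json, file.path(out_dir, "report.json"))

  log_lines <- c(
    sprintf("records: %d", report$provenance$n_records),
    sprintf("seed: %s", report$provenance$seed %||% "none"),
    sprintf("n_boot: %d, n_boot_auc: %d",
            report$provenance$n_boot, report$provenance$n_boot_auc),
    purrr::imap_chr(report$provenance$pair_logs, function(lg, nm) {
      sprintf(
        "pairs[%s]: %d usable of %d consecutive intervals (%d excluded incomplete); improved_any %d, improved_one %d, not improved %d",
        nm, lg$pairs, lg$consecutive_intervals, lg$excluded_incomplete,
        lg$n_improved_any, lg$n_improved_one, lg$n_not_improved
      )
    })
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Write the default analysis config for a cohort
#'
#' Convenience used by the simulation CLI: serialises instrument definitions
#' and analysis defaults to YAML.
#'
#' @param instruments Named list of [instrument()] objects.
#' @param path Output YAML path.
#' @param ... Extra top-level keys (e.g. `seed`, `n_boot`).
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(instruments, path, ...) {
  spec <- purrr::map(instruments, function(ins) {
    out <- list(scale_min = ins$scale_min, scale_max = ins$scale_max,
                direction = ins$direction)
    if (!is.null(ins$resolution)) out$resolution <- ins$resolution
    out
  })
  names(spec) <- vapply(instruments, `[[`, "", "name")
  yaml::write_yaml(c(list(instruments = spec), list(...)), path)
  invisible(path)
}
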