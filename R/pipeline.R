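#' Simulate a cohort and write its trial log, manifest and subject table
#'
#' End-to-end simulation entry point: builds (or loads) the experiment
#' configuration, simulates a cohort, optionally simulates the matching
#' prior-free control task for the same subjects, and writes everything to
#' `out_dir` together with a reproducibility manifest (config hash, seeds,
#' package version, file list).
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; identical `(config, seed)` runs produce
#'   byte-identical outputs.
#' @param n_subjects Cohort size.
#' @param strategy Observer strategy (recycled; see [observer_params()]).
#' @param params A [cohort_params()].
#' @param config Optional [schedule_config()] (e.g. from [read_config()])
#'   overriding `experiment`.
#' @param control Also simulate a control session per subject
#'   (`n_control_trials` per likelihood).
#' @param n_control_trials Control trials per likelihood condition.
#' @return Invisibly, a list with the written paths and the cohort log.
#' @export
run_simulate <- function(experiment = "exp1", out_dir = ".", seed = 1L,
                         n_subjects = 12, strategy = "bayes_transfer",
                         params = cohort_params(), config = NULL,
                         control = FALSE, n_control_trials = 200) {
  if (is.null(config)) config <- default_config(experiment)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- generate_cohort(n_subjects = n_subjects, strategy = strategy,
                         params = params, seed = seed, config = config)
  subjects <- cohort_subjects(log)

  log_path <- file.path(out_dir, paste0(config$experiment, "_cohort.csv"))
  subj_path <- file.path(out_dir, paste0(config$experiment, "_subjects.csv"))
  write_trial_log(log, log_path)
  readr::write_csv(subjects, subj_path)
  paths <- list(log = log_path, subjects = subj_path)

  if (control) {
    ctl <- generate_control_cohort(subjects,
                                   n_per_likelihood = n_control_trials,
                                   likelihoods = config$likelihoods,
                                   sd_mode = config$sd_mode,
                                   seed = seed + 1L)
    ctl_path <- file.path(out_dir, paste0(config$experiment, "_control.csv"))
    readr::write_csv(ctl, ctl_path)
    paths$control <- ctl_path
  }

  manifest <- list(
    tool = "bayestransfer",
    version = as.character(utils::packageVersion("bayestransfer")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    experiment = config$experiment,
    config_hash = rlang::hash(unclass(config)),
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    strategy = unique(strategy),
    outputs = unname(unlist(paths))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(c(paths, list(log = log_path, cohort = log)))
}

#' Run the full analysis chain on a trial log
#'
#' The analysis pipeline: top-1% outlier exclusion, weight regression at the
#' requested grain, centroid-estimator R-squared comparison, prior-only
#' summaries, and — when a control log is available — internal-noise
#' estimation, three-model weight predictions, MSE model comparison, and the
#' transfer contrast (skipped with a note when the log has no high-likelihood
#' trials). Results are written as CSV tables plus one JSON run summary.
#'
#' @param log A trial-log tibble or a path to one (see [read_trial_log()]).
#' @param out_dir Output directory.
#' @param grain Regression grain, `"block"` or `"pooled"`.
#' @param min_trials Minimum trials per regression cell.
#' @param control A control-task log tibble or path, or `NULL`.
#' @param priors,likelihoods Condition tables the log was generated under.
#' @param n_boot Bootstrap resamples for the transfer contrast.
#' @param seed Seed for the bootstrap.
#' @return Invisibly, the full results list (also serialized to
#'   `summary.json`).
#' @export
run_analyze <- function(log, out_dir = ".", grain = "block", min_trials = 10,
                        control = NULL,
                        priors = default_priors(),
                        likelihoods = default_likelihoods(),
                        n_boot = 10000, seed = 1L) {
  if (is.character(log)) log <- read_trial_log(log)
  needed <- c("kind", "prior_id", "likelihood_id", "target_x", "centroid",
              "response_x", "abs_error")
  missing <- setdiff(needed, names(log))
  if (length(missing)) {
    stop("trial log lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(control)) control <- read_trial_log(control)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  excl <- exclude_outliers(log)
  weights <- fit_weights(excl$log, grain = grain, min_trials = min_trials)
  r2 <- estimator_r2(excl$log)
  po <- prior_only_summary(excl$log, priors = priors)

  sigma_li <- NULL
  mse <- NULL
  predictions <- NULL
  if (!is.null(control)) {
    sigma_li <- estimate_internal_noise(control, per_condition = TRUE)
    predictions <- model_predictions(sigma_li, priors = priors,
                                     likelihoods = likelihoods)
    mse <- model_mse(weights, predictions)
  }

  transfer <- NULL
  transfer_note <- NULL
  has_high <- any(weights$likelihood_id == "high" & weights$fitted,
                  na.rm = TRUE)
  if (grain == "block" && has_high) {
    transfer <- transfer_contrast(weights, n_boot = n_boot, seed = seed)
  } else {
    transfer_note <- if (!has_high) {
      "not applicable: no fitted high-likelihood cells in this log"
    } else {
      "not applicable: transfer contrast requires block-grain weights"
    }
  }

  readr::write_csv(weights, file.path(out_dir, "weights.csv"))
  readr::write_csv(r2, file.path(out_dir, "estimator_r2.csv"))
  readr::write_csv(po$summary, file.path(out_dir, "prior_only.csv"))
  readr::write_csv(excl$pairing_report, file.path(out_dir, "exclusions.csv"))
  if (!is.null(predictions)) {
    readr::write_csv(predictions, file.path(out_dir, "model_predictions.csv"))
  }
  if (!is.null(mse)) {
    readr::write_csv(mse, file.path(out_dir, "model_mse.csv"))
  }

  results <- list(
    schema = "bayestransfer-summary v1",
    grain = grain,
    weights = weights,
    estimator_r2 = r2,
    best_estimator = attr(r2, "best"),
    prior_only = po$summary,
    exclusions = excl$pairing_report,
    exclusions_by_subject = excl$subject_report,
    sigma_li = sigma_li,
    model_predictions = predictions,
    model_mse = mse,
    transfer = transfer,
    transfer_note = transfer_note
  )
  jsonlite::write_json(results, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(results)
}

#' Render a human-readable report from an analysis summary
#'
#' Produces a markdown report: mean empirical weight per (prior, likelihood)
#' condition and block — the layout of the study's weight-by-block figures —
#' with the three model-predicted reference weights alongside (the analogue of
#' the figures' dashed lines), the estimator R-squared ranking, prior-only
#' summaries, the model MSE ranking and the transfer contrast.
#'
#' @param summary Path to a `summary.json` written by [run_analyze()], or the
#'   results list itself.
#' @param out_path Optional file to write the markdown to.
#' @return The report as a character vector of lines, invisibly if
#'   `out_path` is given.
#' @export
run_report <- function(summary, out_path = NULL) {
  if (is.character(summary)) {
    if (!file.exists(summary)) {
      stop("summary file not found: ", summary, call. = FALSE)
    }
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
    if (!is.null(summary$schema) &&
        !identical(summary$schema, "bayestransfer-summary v1")) {
      warning("summary schema version mismatch: ", summary$schema)
    }
  }
  fmt <- function(x) {
    if (is.null(x) || !length(x)) return("NA")
    x <- suppressWarnings(as.numeric(unlist(x)))
    ifelse(is.na(x), "NA", formatC(x, digits = 3, format = "f"))
  }
  lines <- c("# Localization cohort report", "")

  w <- tibble::as_tibble(summary$weights)
  w <- w[!is.na(w$slope), , drop = FALSE]
  if (!nrow(w)) {
    lines <- c(lines, "No fitted weight cells.", "")
    if (is.null(out_path)) return(lines)
    writeLines(lines, out_path)
    return(invisible(lines))
  }

  preds <- if (!is.null(summary$model_predictions)) {
    tibble::as_tibble(summary$model_predictions) |>
      dplyr::group_by(.data$prior_id, .data$likelihood_id) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("w_"),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  } else {
    NULL
  }

  lines <- c(lines, "## Mean weight on the likelihood", "")
  has_block <- "block" %in% names(w)
  cell_means <- w |>
    dplyr::group_by(!!!rlang::syms(c("prior_id", "likelihood_id",
                                     if (has_block) "block"))) |>
    dplyr::summarise(weight = mean(.data$slope), .groups = "drop")
  if (has_block) {
    wide <- tidyr::pivot_wider(cell_means, names_from = "block",
                               values_from = "weight",
                               names_prefix = "block ", names_sort = TRUE)
  } else {
    wide <- cell_means
  }
  if (!is.null(preds)) {
    wide <- dplyr::left_join(wide, preds, by = c("prior_id", "likelihood_id"))
  }
  hdr <- names(wide)
  rows <- apply(wide, 1, function(r) {
    vals <- vapply(seq_along(r), function(j) {
      x <- suppressWarnings(as.numeric(r[[j]]))
      if (is.na(x)) as.character(r[[j]]) else fmt(x)
    }, character(1))
    paste0("| ", paste(vals, collapse = " | "), " |")
  })
  lines <- c(lines,
             paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
             rows, "")
  if (!is.null(preds)) {
    lines <- c(lines,
               paste("Reference columns: `w_external` (ideal weighting by the",
                     "imposed cue variance), `w_internal` (weighting by",
                     "internal noise only), `w_overall` (weighting by their",
                     "sum)."),
               "")
  }

  if (!is.null(summary$estimator_r2)) {
    r2 <- tibble::as_tibble(summary$estimator_r2)
    lines <- c(lines, "## Centroid estimator comparison (R^2)", "",
               paste0("- ", r2$estimator, ": ", fmt(r2$r2)),
               paste0("- best: **", summary$best_estimator, "**"), "")
  }

  if (!is.null(summary$prior_only)) {
    po <- tibble::as_tibble(summary$prior_only)
    lines <- c(lines, "## Prior-only trials", "",
               sprintf("- %s prior: mean bias %s psw, median response SD %s (true SD %s)",
                       po$prior_id, fmt(po$mean_bias), fmt(po$median_sd),
                       fmt(po$true_sigma_p)), "")
  }

  if (!is.null(summary$model_mse)) {
    m <- tibble::as_tibble(summary$model_mse)
    lines <- c(lines, "## Model comparison (ascending MSE)", "",
               sprintf("%d. %s model: MSE %s (%d cells)", seq_len(nrow(m)),
                       m$model, formatC(m$mse, digits = 4, format = "f"),
                       m$n_cells), "")
  }

  if (!is.null(summary$transfer)) {
    tr <- summary$transfer
    lines <- c(lines, "## Transfer contrast", "",
               sprintf("- first block with the high likelihood: %d",
                       tr$first_high_block),
               sprintf("- immediate gap, weight(medium) - weight(high): %s [%s, %s]",
                       fmt(tr$immediate_gap$mean), fmt(tr$immediate_gap$ci[1]),
                       fmt(tr$immediate_gap$ci[2])),
               sprintf("- exposure slope of weight(high) to the next block: %s [%s, %s]",
                       fmt(tr$exposure_slope$mean),
                       fmt(tr$exposure_slope$ci[1]),
                       fmt(tr$exposure_slope$ci[2])),
               "")
  } else if (!is.null(summary$transfer_note)) {
    lines <- c(lines, "## Transfer contrast", "",
               paste0("- ", summary$transfer_note), "")
  }

  if (is.null(out_path)) return(lines)
  writeLines(lines, out_path)
  invisible(lines)
}
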