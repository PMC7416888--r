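#' Top-1% absolute-error outlier exclusion
#'
#' For each (prior, likelihood) pairing — pooling across blocks and subjects —
#' main trials whose absolute error lies strictly above the pairing's 99th
#' percentile of absolute errors are dropped. The percentile uses linear
#' interpolation ([stats::quantile()] type 7) and exclusion is by strict
#' inequality, so a degenerate pairing in which all errors are equal drops
#' nothing; per-pairing drops are bounded by 1% of the pairing's trials.
#' Prior-only rows are never dropped.
#'
#' @param log A trial-log tibble with `kind`, `prior_id`, `likelihood_id` and
#'   `abs_error` columns.
#' @param percentile Exclusion percentile (default 0.99).
#' @return List with `log` (filtered), `pairing_report` (per-pairing `n`,
#'   `threshold`, `n_dropped`) and `subject_report` (drop counts per subject
#'   and pairing, including the per-subject maximum over pairings).
#' @export
exclude_outliers <- function(log, percentile = 0.99) {
  main <- log[log$kind == "main", , drop = FALSE]
  if (!nrow(main)) {
    warning("log contains no main trials; nothing to exclude")
    return(list(log = log, pairing_report = tibble::tibble(),
                subject_report = tibble::tibble()))
  }
  main <- main |>
    dplyr::group_by(.data$prior_id, .data$likelihood_id) |>
    dplyr::mutate(
      .threshold = stats::quantile(.data$abs_error, percentile, type = 7,
                                   names = FALSE),
      .drop = .data$abs_error > .data$.threshold
    ) |>
    dplyr::ungroup()

  pairing_report <- main |>
    dplyr::group_by(.data$prior_id, .data$likelihood_id) |>
    dplyr::summarise(n = dplyr::n(),
                     threshold = .data$.threshold[1],
                     n_dropped = sum(.data$.drop), .groups = "drop")

  subject_report <- if ("subject_id" %in% names(main)) {
    per <- main |>
      dplyr::group_by(.data$subject_id, .data$prior_id,
                      .data$likelihood_id) |>
      dplyr::summarise(n_dropped = sum(.data$.drop), .groups = "drop")
    per |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(total_dropped = sum(.data$n_dropped),
                       max_dropped_per_pairing = max(.data$n_dropped),
                       .groups = "drop")
  } else {
    tibble::tibble()
  }

  kept_main <- main[!main$.drop, , drop = FALSE]
  kept_main$.threshold <- NULL
  kept_main$.drop <- NULL
  out <- dplyr::bind_rows(kept_main, log[log$kind != "main", , drop = FALSE])
  ord_cols <- intersect(c("subject_id", "trial_index"), names(out))
  if (length(ord_cols)) out <- dplyr::arrange(out, !!!rlang::syms(ord_cols))
  list(log = out, pairing_report = pairing_report,
       subject_report = subject_report)
}

#' Weight regression: response on centroid
#'
#' For each analysis cell, responses are regressed on dot-cloud centroids by
#' ordinary least squares. The slope is the weight placed on the likelihood
#' (1 = cue-only, 0 = prior-only responding) and the intercept approximates
#' `(1 - w) * prior_mean`. Slopes are not constrained to \[0, 1\] by the fit;
#' values outside \[-0.2, 1.2\] are flagged. Cells with fewer than
#' `min_trials` trials, or with constant centroid (singular design), are
#' flagged and not fitted.
#'
#' @param log A trial-log tibble (main trials are used).
#' @param grain `"block"` for per-(subject, prior, likelihood, block) cells —
#'   the grain behind block-resolved weight figures — or `"pooled"` to pool
#'   over blocks.
#' @param min_trials Minimum trials per fitted cell (default 10).
#' @return A tibble of weight estimates: grouping columns plus `n_trials`,
#'   `slope`, `intercept`, `r2`, `fitted` (logical) and `flag`
#'   (`"ok"`, `"too_few_trials"`, `"singular"`, `"slope_outside_[-0.2,1.2]"`).
#' @examples
#' log <- generate_cohort("exp1", 1, "ideal_bayes", seed = 2)
#' fit_weights(log, grain = "pooled")
#' @export
fit_weights <- function(log, grain = c("block", "pooled"), min_trials = 10) {
  grain <- match.arg(grain)
  main <- log[log$kind == "main", , drop = FALSE]
  if (!nrow(main)) stop("log contains no main trials", call. = FALSE)
  keys <- c(if ("subject_id" %in% names(main)) "subject_id",
            "prior_id", "likelihood_id", if (grain == "block") "block")
  main |>
    dplyr::group_by(!!!rlang::syms(keys)) |>
    dplyr::group_modify(function(d, g) {
      n <- nrow(d)
      if (n < min_trials) {
        return(tibble::tibble(n_trials = n, slope = NA_real_,
                              intercept = NA_real_, r2 = NA_real_,
                              fitted = FALSE, flag = "too_few_trials"))
      }
      if (stats::var(d$centroid) == 0) {
        return(tibble::tibble(n_trials = n, slope = NA_real_,
                              intercept = NA_real_, r2 = NA_real_,
                              fitted = FALSE, flag = "singular"))
      }
      fit <- stats::lm(response_x ~ centroid, data = d)
      cf <- stats::coef(fit)
      # simple-regression R^2; avoids summary.lm()'s perfect-fit warning on
      # noiseless simulated cells
      r2 <- if (stats::var(d$response_x) == 0) 1
            else stats::cor(d$response_x, d$centroid)^2
      flag <- if (cf[2] < -0.2 || cf[2] > 1.2) "slope_outside_[-0.2,1.2]"
              else "ok"
      tibble::tibble(n_trials = n, slope = unname(cf[2]),
                     intercept = unname(cf[1]), r2 = r2, fitted = TRUE,
                     flag = flag)
    }) |>
    dplyr::ungroup()
}

#' Compare candidate centroid estimators by R-squared
#'
#' Pooled across subjects, blocks and trial types, responses are regressed on
#' each estimate an observer could have taken from the cloud (arithmetic mean,
#' robust average, median, mid-range); the estimator with the highest
#' R-squared is the one the responses most likely relied on.
#'
#' @param log A trial-log tibble whose main trials carry dot columns
#'   (`dot_x_1..`).
#' @param trim_k Trim threshold for the robust average.
#' @return A tibble (`estimator`, `r2`) sorted by decreasing `r2`, with the
#'   winning estimator name in attribute `"best"`.
#' @export
estimator_r2 <- function(log, trim_k = 2) {
  main <- log[log$kind == "main", , drop = FALSE]
  dot_cols <- grep("^dot_x_", names(main), value = TRUE)
  if (!length(dot_cols)) {
    stop("log lacks dot position columns (dot_x_*)", call. = FALSE)
  }
  dots <- as.matrix(main[, dot_cols])
  mids <- (apply(dots, 1, min) + apply(dots, 1, max)) / 2
  ests <- tibble::tibble(
    mean = rowMeans(dots),
    median = apply(dots, 1, stats::median),
    midrange = mids,
    robust_average = apply(dots, 1, robust_average, trim_k = trim_k)
  )
  r2 <- vapply(ests, function(e) stats::cor(main$response_x, e)^2, numeric(1))
  out <- tibble::tibble(estimator = names(r2), r2 = unname(r2)) |>
    dplyr::arrange(dplyr::desc(.data$r2))
  attr(out, "best") <- out$estimator[1]
  out
}

#' Summaries of prior-only trials
#'
#' Prior-only responses reveal the learned prior: per subject and prior the
#' mean response bias (mean response minus the true prior mean) and the
#' response SD; across subjects, the mean bias with a one-sample t-test
#' against zero and the median of the subject response SDs, reported next to
#' the true prior SD.
#'
#' @param log A trial-log tibble containing prior-only rows.
#' @param priors Prior condition table supplying `mu_p`/`sigma_p`.
#' @return List with `by_subject` (subject x prior `n`, `bias`,
#'   `sd_response`) and `summary` (per prior: `mean_bias`, `t`, `p`,
#'   `ci_lo`, `ci_hi`, `median_sd`, `true_sigma_p`).
#' @export
prior_only_summary <- function(log, priors = default_priors()) {
  po <- log[log$kind == "prior_only", , drop = FALSE]
  if (!nrow(po)) stop("log contains no prior-only trials", call. = FALSE)
  missing_p <- setdiff(priors$prior_id, unique(po$prior_id))
  if (length(missing_p)) {
    warning("no prior-only trials for prior(s): ",
            paste(missing_p, collapse = ", "), "; omitted")
  }
  if (!"subject_id" %in% names(po)) po$subject_id <- "S01"
  by_subject <- po |>
    dplyr::left_join(priors[, c("prior_id", "mu_p")], by = "prior_id") |>
    dplyr::group_by(.data$subject_id, .data$prior_id) |>
    dplyr::summarise(n = dplyr::n(),
                     bias = mean(.data$response_x) - .data$mu_p[1],
                     sd_response = stats::sd(.data$response_x),
                     .groups = "drop")
  summary <- by_subject |>
    dplyr::group_by(.data$prior_id) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_bias = mean(.data$bias),
      t = if (dplyr::n() >= 2 && stats::sd(.data$bias) > 0) {
        unname(stats::t.test(.data$bias)$statistic)
      } else NA_real_,
      p = if (dplyr::n() >= 2 && stats::sd(.data$bias) > 0) {
        stats::t.test(.data$bias)$p.value
      } else NA_real_,
      ci_lo = if (dplyr::n() >= 2 && stats::sd(.data$bias) > 0) {
        stats::t.test(.data$bias)$conf.int[1]
      } else NA_real_,
      ci_hi = if (dplyr::n() >= 2 && stats::sd(.data$bias) > 0) {
        stats::t.test(.data$bias)$conf.int[2]
      } else NA_real_,
      median_sd = stats::median(.data$sd_response),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      priors |> dplyr::select("prior_id", true_sigma_p = "sigma_p"),
      by = "prior_id"
    )
  list(by_subject = by_subject, summary = summary)
}

#' Estimate internal noise from the control task
#'
#' The internal variability in using the cue is estimated as the SD of the
#' centroid-to-response error (`centroid - response`) over control-task trials,
#' per subject and — if `per_condition` — per likelihood level. The estimator
#' necessarily conflates centroid-estimation noise with motor noise; simulated
#' observers keep the two separate, and a generating `(sigma_li, sigma_m)`
#' pair is recovered here as `sqrt(sigma_li^2 + sigma_m^2)`.
#'
#' @param control_log A [generate_control_session()]-schema tibble (needs
#'   `centroid` and `response_x`; `subject_id`/`likelihood_id` if present are
#'   used for grouping).
#' @param per_condition Estimate per likelihood condition (default) or pooled.
#' @return Tibble with `subject_id` (and `likelihood_id` if per-condition),
#'   `n` and `sigma_li_hat`.
#' @export
estimate_internal_noise <- function(control_log, per_condition = TRUE) {
  if (!all(c("centroid", "response_x") %in% names(control_log))) {
    stop("control log needs `centroid` and `response_x` columns",
         call. = FALSE)
  }
  if (!"subject_id" %in% names(control_log)) control_log$subject_id <- "S01"
  keys <- c("subject_id",
            if (per_condition && "likelihood_id" %in% names(control_log)) {
              "likelihood_id"
            })
  out <- control_log |>
    dplyr::group_by(!!!rlang::syms(keys)) |>
    dplyr::summarise(
      n = dplyr::n(),
      sigma_li_hat = stats::sd(.data$centroid - .data$response_x),
      .groups = "drop"
    )
  if (any(out$n < 3)) {
    stop("need at least 3 control trials per cell to estimate internal noise",
         call. = FALSE)
  }
  out
}

#' Predicted weights for the three observer models
#'
#' Per subject and (prior, likelihood) condition, the weight on the likelihood
#' predicted by the external-noise (ideal) model, the internal-noise-only
#' model, and the overall-variability model (see [optimal_weight()]). The
#' internal and overall predictions need a per-subject internal-noise
#' estimate; if `sigma_li` is `NULL` those columns are `NA` with a warning.
#'
#' @param sigma_li Tibble from [estimate_internal_noise()] (columns
#'   `subject_id`, optionally `likelihood_id`, and `sigma_li_hat`), or `NULL`.
#' @param priors,likelihoods Condition tables.
#' @return Tibble: `subject_id`, `prior_id`, `likelihood_id`, `w_external`,
#'   `w_internal`, `w_overall`.
#' @export
model_predictions <- function(sigma_li = NULL,
                              priors = default_priors(),
                              likelihoods = default_likelihoods()) {
  grid <- tidyr::expand_grid(
    subject_id = if (is.null(sigma_li)) "S01" else unique(sigma_li$subject_id),
    prior_id = priors$prior_id,
    likelihood_id = likelihoods$likelihood_id
  ) |>
    dplyr::left_join(priors[, c("prior_id", "sigma_p")], by = "prior_id") |>
    dplyr::left_join(likelihoods[, c("likelihood_id", "sigma_l", "n_dots")],
                     by = "likelihood_id")
  grid$w_external <- optimal_weight(grid$sigma_l, grid$n_dots, grid$sigma_p)
  if (is.null(sigma_li)) {
    warning("no sigma_li estimates supplied; internal/overall predictions NA")
    grid$w_internal <- NA_real_
    grid$w_overall <- NA_real_
  } else {
    by <- c("subject_id",
            if ("likelihood_id" %in% names(sigma_li)) "likelihood_id")
    grid <- dplyr::left_join(grid, sigma_li[, c(by, "sigma_li_hat")], by = by)
    grid$w_internal <- internal_noise_weight(grid$sigma_li_hat, grid$sigma_p)
    grid$w_overall <- overall_variability_weight(grid$sigma_l, grid$n_dots,
                                                 grid$sigma_li_hat,
                                                 grid$sigma_p)
    grid$sigma_li_hat <- NULL
  }
  dplyr::select(grid, "subject_id", "prior_id", "likelihood_id",
                "w_external", "w_internal", "w_overall")
}

#' Model comparison by mean squared error
#'
#' Empirical weights (regression slopes) are compared with each model's
#' predicted weights over matched (subject, prior, likelihood) cells; models
#' are ranked by ascending MSE. By default the final-block weights are used,
#' mirroring end-of-training behaviour.
#'
#' @param weights A [fit_weights()] table.
#' @param predictions A [model_predictions()] table.
#' @param blocks Blocks to keep (default: the maximum block present; ignored
#'   for pooled weight tables).
#' @return Tibble (`model`, `mse`, `n_cells`) in ascending MSE order.
#' @export
model_mse <- function(weights, predictions, blocks = NULL) {
  w <- weights[weights$fitted & !is.na(weights$slope), , drop = FALSE]
  if ("block" %in% names(w) && nrow(w)) {
    if (is.null(blocks)) blocks <- max(w$block)
    w <- w[w$block %in% blocks, , drop = FALSE]
  }
  by <- intersect(c("subject_id", "prior_id", "likelihood_id"),
                  intersect(names(w), names(predictions)))
  cells <- dplyr::inner_join(w, predictions, by = by)
  if (!nrow(cells)) stop("no matched (subject, condition) cells", call. = FALSE)
  tibble::tibble(
    model = c("external", "internal", "overall"),
    mse = c(mean((cells$slope - cells$w_external)^2),
            mean((cells$slope - cells$w_internal)^2),
            mean((cells$slope - cells$w_overall)^2)),
    n_cells = nrow(cells)
  ) |>
    dplyr::arrange(.data$mse)
}

#' Transfer contrast over the blocks where the high likelihood appears
#'
#' Two signatures distinguish a Bayesian-transfer observer from a rote
#' learner once a new, noisier likelihood level is introduced:
#'
#' * `immediate_gap` — per-subject weight(medium) minus weight(high),
#'   averaged over priors, in the *first* block containing high-likelihood
#'   trials. Positive with a CI excluding zero indicates immediate
#'   down-weighting (transfer); a CI containing zero indicates none.
#' * `exposure_slope` — per-subject change in weight(high) from that block to
#'   the next. A negative drift with increasing exposure is the rote-learning
#'   signature; a CI containing zero indicates no feedback-driven change.
#'
#' Both use a nonparametric bootstrap over subjects (percentile CI).
#'
#' @param weights A [fit_weights()] table at block grain.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `first_high_block` and, for each contrast, the subject
#'   values, mean, and bootstrap CI.
#' @export
transfer_contrast <- function(weights, n_boot = 10000, conf = 0.95,
                              seed = 1L) {
  if (!"block" %in% names(weights)) {
    stop("transfer_contrast needs block-grain weights", call. = FALSE)
  }
  w <- weights[weights$fitted & !is.na(weights$slope), , drop = FALSE]
  if (!"subject_id" %in% names(w)) w$subject_id <- "S01"
  high <- w[w$likelihood_id == "high", , drop = FALSE]
  if (!nrow(high)) stop("no high-likelihood cells in weight table",
                        call. = FALSE)
  b1 <- min(high$block)
  b2 <- b1 + 1L

  per_subject_mean <- function(d) {
    stats::setNames(
      tapply(d$slope, d$subject_id, mean),
      NULL
    )
  }
  cell <- function(lik, blk) {
    d <- w[w$likelihood_id == lik & w$block == blk, , drop = FALSE]
    tapply(d$slope, d$subject_id, mean)
  }
  med1 <- cell("medium", b1)
  hi1 <- cell("high", b1)
  subj_gap <- intersect(names(med1), names(hi1))
  gap <- as.numeric(med1[subj_gap] - hi1[subj_gap])

  hi2 <- cell("high", b2)
  subj_slope <- intersect(names(hi1), names(hi2))
  slope <- as.numeric(hi2[subj_slope] - hi1[subj_slope])

  boot_ci <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_))
    if (length(x) == 1) return(c(x, x))
    means <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    unname(stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                           type = 7))
  }
  set.seed(as.integer(seed))
  gap_ci <- boot_ci(gap)
  slope_ci <- boot_ci(slope)

  list(
    first_high_block = b1,
    immediate_gap = list(per_subject = gap, mean = mean(gap),
                         ci = gap_ci, n_subjects = length(gap)),
    exposure_slope = list(per_subject = slope,
                          mean = if (length(slope)) mean(slope) else NA_real_,
                          ci = slope_ci, n_subjects = length(slope))
  )
}
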