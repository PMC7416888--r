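#' Cohort-level simulation parameters
#'
#' Distributions from which per-subject observer parameters are drawn.
#' Internal noise `sigma_li` is log-normal per likelihood condition around the
#' given medians; the defaults (0.5, 1.3, 2.5 psw for low/medium/high) exceed
#' the true cue variability `sigma_l / sqrt(8)` = 0.21/1.06/2.12 psw in the low
#' and medium conditions, matching how control-task performance compares to an
#' ideal averager. Motor noise is log-normal around 0.5 psw.
#'
#' @param sigma_li_median Named medians of internal noise per likelihood, psw.
#' @param sigma_li_sdlog Log-scale SD of per-subject internal-noise draws.
#' @param sigma_m_median,sigma_m_sdlog Motor-noise log-normal parameters, psw.
#' @param learn_rate Look-up-table delta-rule step size (see
#'   [observer_params()]).
#' @param transfer_rule `"optimal"` or `"internal"` (Bayesian-transfer
#'   observers).
#' @param fixed_w Weight(s) for `fixed_weight` cohorts.
#' @param prior_init_mean,prior_init_sd,prior_only_mode Passed to
#'   [observer_params()].
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(sigma_li_median = c(low = 0.5, medium = 1.3,
                                              high = 2.5),
                          sigma_li_sdlog = 0.2,
                          sigma_m_median = 0.5, sigma_m_sdlog = 0.2,
                          learn_rate = 2e-5,
                          transfer_rule = "optimal",
                          fixed_w = NULL,
                          prior_init_mean = 50, prior_init_sd = 5,
                          prior_only_mode = "sample") {
  structure(
    list(sigma_li_median = sigma_li_median, sigma_li_sdlog = sigma_li_sdlog,
         sigma_m_median = sigma_m_median, sigma_m_sdlog = sigma_m_sdlog,
         learn_rate = learn_rate, transfer_rule = transfer_rule,
         fixed_w = fixed_w, prior_init_mean = prior_init_mean,
         prior_init_sd = prior_init_sd, prior_only_mode = prior_only_mode),
    class = "cohort_params"
  )
}

draw_subjects <- function(n_subjects, strategy, params) {
  strategies <- rep_len(strategy, n_subjects)
  li <- params$sigma_li_median
  draws <- vapply(seq_len(n_subjects), function(i) {
    li * stats::rlnorm(length(li), 0, params$sigma_li_sdlog)
  }, numeric(length(li)))
  draws <- matrix(draws, nrow = length(li))
  rownames(draws) <- names(li)
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    strategy = strategies,
    !!!stats::setNames(
      lapply(names(li), function(nm) draws[nm, ]),
      paste0("sigma_li_", names(li))
    ),
    sigma_m = stats::rlnorm(n_subjects, log(params$sigma_m_median),
                            params$sigma_m_sdlog),
    schedule_seed = sample.int(.Machine$integer.max - 1L, n_subjects),
    session_seed = sample.int(.Machine$integer.max - 1L, n_subjects)
  )
}

subject_observer <- function(subject, params) {
  li_cols <- grep("^sigma_li_", names(subject), value = TRUE)
  sigma_li <- stats::setNames(as.numeric(subject[1, li_cols]),
                              sub("^sigma_li_", "", li_cols))
  observer_params(
    strategy = subject$strategy,
    sigma_li = sigma_li,
    sigma_m = subject$sigma_m,
    learn_rate = params$learn_rate,
    fixed_w = params$fixed_w,
    transfer_rule = params$transfer_rule,
    prior_init_mean = params$prior_init_mean,
    prior_init_sd = params$prior_init_sd,
    prior_only_mode = params$prior_only_mode
  )
}

#' Simulate a full session for one observer
#'
#' Runs the per-trial response model over a schedule. Stateless strategies
#' (`ideal_bayes`, `fixed_weight`) are simulated vectorized; learning
#' strategies run the sequential loop so that prior beliefs and look-up
#' weights evolve with feedback.
#'
#' @param observer An [observer_params()].
#' @param schedule A [build_schedule()] tibble.
#' @param priors,likelihoods Condition tables (must match the schedule).
#' @param seed Integer seed for the response noise stream.
#' @return The schedule tibble with columns `response_x`, `w_used`, `error`
#'   (`response_x - target_x`), `abs_error` and `caught` appended.
#' @export
simulate_session <- function(observer, schedule,
                             priors = default_priors(),
                             likelihoods = default_likelihoods(),
                             seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  is_main <- schedule$kind == "main"
  n_dots <- likelihoods$n_dots[1]

  s_li <- rep(0, n)
  s_li[is_main] <- vapply(schedule$likelihood_id[is_main],
                          function(l) sigma_li_for(observer, l), numeric(1))
  true_mu <- priors$mu_p[match(schedule$prior_id, priors$prior_id)]
  true_sd <- priors$sigma_p[match(schedule$prior_id, priors$prior_id)]

  if (observer$strategy %in% c("ideal_bayes", "fixed_weight")) {
    w <- rep(NA_real_, n)
    if (observer$strategy == "ideal_bayes") {
      s_l <- likelihoods$sigma_l[match(schedule$likelihood_id,
                                       likelihoods$likelihood_id)]
      w[is_main] <- optimal_weight(s_l[is_main], n_dots, true_sd[is_main])
    } else {
      w[is_main] <- vapply(schedule$likelihood_id[is_main],
                           function(l) fixed_w_for(observer, l), numeric(1))
    }
    pc <- schedule$centroid + stats::rnorm(n, 0, s_li)
    response <- w * pc + (1 - w) * true_mu
    po <- !is_main
    response[po] <- if (observer$prior_only_mode == "sample") {
      stats::rnorm(sum(po), true_mu[po], true_sd[po])
    } else {
      true_mu[po]
    }
    response <- response + stats::rnorm(n, 0, observer$sigma_m)
  } else {
    # Sequential loop over trials; plain vectors for speed.
    kind <- schedule$kind
    prior_id <- schedule$prior_id
    likelihood_id <- schedule$likelihood_id
    target_x <- schedule$target_x
    centroid <- schedule$centroid
    cloud_sd <- rep(NA_real_, n)
    if (observer$strategy == "bayes_transfer" &&
        observer$transfer_rule == "optimal") {
      dotm <- as.matrix(schedule[, paste0("dot_x_", seq_len(n_dots))])
      mu_row <- rowMeans(dotm)
      cloud_sd <- sqrt(rowMeans((dotm - mu_row)^2))  # population form
    }
    response <- numeric(n)
    w <- rep(NA_real_, n)
    state <- new_observer_state(observer, priors)
    for (i in seq_len(n)) {
      res <- simulate_one(observer, state, kind = kind[i],
                          prior_id = prior_id[i],
                          likelihood_id = likelihood_id[i],
                          target_x = target_x[i], centroid = centroid[i],
                          cloud_sd = cloud_sd[i],
                          priors = priors, likelihoods = likelihoods)
      response[i] <- res$response_x
      w[i] <- res$w
      state <- res$state
    }
  }

  out <- schedule
  out$response_x <- response
  out$w_used <- w
  out$error <- response - schedule$target_x
  out$abs_error <- abs(out$error)
  out$caught <- catch_and_score(response, schedule$target_x)$caught
  out
}

#' Generate a synthetic cohort trial log
#'
#' Stand-in for a behavioural data set: for each simulated subject an
#' independent schedule is built (fresh seed), an observer initialized, and a
#' complete session simulated. Deterministic given `(config, seed)`.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"` (ignored if `config`
#'   given). Cohort sizes in the source study were 26, 12 and 12.
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param strategy Observer strategy label, recycled over subjects (a vector
#'   gives a strategy mix).
#' @param params A [cohort_params()].
#' @param seed Integer master seed.
#' @param config Optional explicit [schedule_config()] overriding
#'   `experiment`.
#' @return A trial-log tibble (one row per trial per subject) with columns
#'   `subject_id`, `strategy`, the schedule columns, `response_x`, `w_used`,
#'   `error`, `abs_error`, `caught` and `seed_tag`. The per-subject parameter
#'   draws are attached as attribute `"subjects"` (also via
#'   [cohort_subjects()]).
#' @examples
#' log <- generate_cohort("exp1", n_subjects = 2, strategy = "ideal_bayes",
#'                        seed = 7)
#' nrow(log) / 2  # 1666 = 1500 main + 166 prior-only trials
#' @export
generate_cohort <- function(experiment = "exp1", n_subjects = 12,
                            strategy = "bayes_transfer",
                            params = cohort_params(), seed = 1L,
                            config = NULL) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  ok <- c("ideal_bayes", "bayes_transfer", "internal_noise", "lookup_table",
          "fixed_weight")
  bad <- setdiff(unique(strategy), ok)
  if (length(bad)) {
    stop("unknown strategy label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config)) config <- default_config(experiment)
  validate_config(config)
  set.seed(as.integer(seed))
  subjects <- draw_subjects(n_subjects, strategy, params)

  logs <- lapply(seq_len(n_subjects), function(i) {
    subj <- subjects[i, ]
    sched <- build_schedule(config, seed = subj$schedule_seed)
    obs <- subject_observer(subj, params)
    sess <- simulate_session(obs, sched, priors = config$priors,
                             likelihoods = config$likelihoods,
                             seed = subj$session_seed)
    sess$subject_id <- subj$subject_id
    sess$strategy <- subj$strategy
    sess$seed_tag <- sprintf("%d/%d", subj$schedule_seed, subj$session_seed)
    sess
  })
  out <- dplyr::bind_rows(logs)
  out <- dplyr::relocate(out, "subject_id", "strategy")
  attr(out, "subjects") <- subjects
  out
}

#' @rdname generate_cohort
#' @param log A trial log produced by [generate_cohort()].
#' @export
cohort_subjects <- function(log) attr(log, "subjects")

#' Simulate the prior-free centroiding control task
#'
#' The control task measures how well an observer locates dot-cloud centroids
#' in the absence of prior structure: targets are scattered uniformly (default
#' over 20-80 psw), a cloud is shown for each of the three likelihood levels,
#' and the response is `centroid + N(0, sigma_li) + N(0, sigma_m)`. The SD of
#' `centroid - response` over these trials is the internal-noise estimate
#' (necessarily conflating centroid-estimation and motor noise).
#'
#' @param n_per_likelihood Trials per likelihood condition (>= 2).
#' @param sigma_li Internal noise SD, psw: scalar or named by likelihood.
#' @param sigma_m Motor noise SD, psw.
#' @param likelihoods Likelihood condition table.
#' @param target_range Uniform target placement range, psw.
#' @param sd_mode SD convention for cloud rescaling.
#' @param seed Integer seed.
#' @param subject_id Label stamped on the rows.
#' @return A control trial-log tibble with `subject_id`, `likelihood_id`,
#'   `target_x`, dot columns, `centroid`, `response_x`, `centroid_error`
#'   (`centroid - response_x`).
#' @export
generate_control_session <- function(n_per_likelihood = 100,
                                     sigma_li = 0, sigma_m = 0,
                                     likelihoods = default_likelihoods(),
                                     target_range = c(20, 80),
                                     sd_mode = "population",
                                     seed = 1L,
                                     subject_id = "S01") {
  if (n_per_likelihood < 2) {
    stop("`n_per_likelihood` must be >= 2", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_dots <- likelihoods$n_dots[1]
  obs <- observer_params("ideal_bayes", sigma_li = sigma_li, sigma_m = sigma_m)
  rows <- lapply(seq_len(nrow(likelihoods)), function(k) {
    lik <- likelihoods[k, ]
    targets <- stats::runif(n_per_likelihood, target_range[1], target_range[2])
    clouds <- lapply(targets, function(t) {
      generate_dot_cloud(t, lik$sigma_l, n_dots, sd_mode)
    })
    centroid <- vapply(clouds, `[[`, numeric(1), "centroid")
    dotx <- do.call(rbind, lapply(clouds, `[[`, "dot_xs"))
    colnames(dotx) <- paste0("dot_x_", seq_len(n_dots))
    s_li <- sigma_li_for(obs, lik$likelihood_id)
    response <- centroid + stats::rnorm(n_per_likelihood, 0, s_li) +
      stats::rnorm(n_per_likelihood, 0, sigma_m)
    dplyr::bind_cols(
      tibble::tibble(subject_id = subject_id,
                     likelihood_id = lik$likelihood_id,
                     target_x = targets, centroid = centroid,
                     response_x = response,
                     centroid_error = centroid - response),
      tibble::as_tibble(dotx)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname generate_control_session
#' @param subjects A subjects table as attached by [generate_cohort()] (needs
#'   `subject_id`, `sigma_li_*` columns and `sigma_m`); one control session is
#'   simulated per row with that subject's noise parameters.
#' @export
generate_control_cohort <- function(subjects, n_per_likelihood = 100,
                                    likelihoods = default_likelihoods(),
                                    target_range = c(20, 80),
                                    sd_mode = "population", seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(subjects))
  li_cols <- grep("^sigma_li_", names(subjects), value = TRUE)
  dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    sigma_li <- stats::setNames(as.numeric(subjects[i, li_cols]),
                                sub("^sigma_li_", "", li_cols))
    generate_control_session(
      n_per_likelihood = n_per_likelihood, sigma_li = sigma_li,
      sigma_m = subjects$sigma_m[i], likelihoods = likelihoods,
      target_range = target_range, sd_mode = sd_mode, seed = seeds[i],
      subject_id = subjects$subject_id[i]
    )
  }))
}

#' Read and write trial logs as CSV
#'
#' Logs are plain CSV with a schema-version header comment
#' (`# bayestransfer-trial-log v1`); `read_trial_log()` accepts gzipped files
#' transparently. A written-then-read log yields identical analysis results.
#'
#' @param log A trial-log tibble.
#' @param path Output (input) file path; `.gz` suffix compresses.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   the tibble.
#' @export
write_trial_log <- function(log, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("# bayestransfer-trial-log v1", con)
  writeLines(readr::format_csv(log), con, sep = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
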