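#' Experiment schedule configuration
#'
#' A `schedule_config` bundles everything the scheduler needs: the prior and
#' likelihood condition tables, the per-block pairing counts, the run length
#' over which target moments are balanced, and the prior-only interleaving
#' period.
#'
#' @param experiment Label `"exp1"`, `"exp2"` or `"exp3"`.
#' @param priors,likelihoods Condition tables as produced by [default_priors()]
#'   and [default_likelihoods()].
#' @param pairings_by_block Tibble with columns `block`, `prior_id`,
#'   `likelihood_id`, `n_trials`; per-block counts must sum to
#'   `main_trials_per_block`.
#' @param n_blocks,main_trials_per_block Block structure.
#' @param run_length Number of consecutive main trials forming one
#'   moment-balanced run (default 20; each prior gets `run_length / 2` slots).
#' @param prior_only_period One prior-only trial is inserted after every
#'   `prior_only_period` main trials, alternating prior identity (default 9).
#' @param sd_mode `"population"` (divide-by-n, the default) or `"sample"`
#'   (divide-by-n-1): the SD convention used when rescaling dot clouds and
#'   moment-correcting run targets. The source study does not state which form
#'   it used; the choice changes the visual dot spread by sqrt(n/(n-1)).
#' @return A list of class `schedule_config`.
#' @export
schedule_config <- function(experiment,
                            priors = default_priors(),
                            likelihoods = default_likelihoods(),
                            pairings_by_block,
                            n_blocks = max(pairings_by_block$block),
                            main_trials_per_block = NULL,
                            run_length = 20L,
                            prior_only_period = 9L,
                            sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  check_priors(priors)
  check_likelihoods(likelihoods)
  if (is.null(main_trials_per_block)) {
    main_trials_per_block <-
      sum(pairings_by_block$n_trials[pairings_by_block$block == 1])
  }
  cfg <- structure(
    list(experiment = experiment,
         priors = priors,
         likelihoods = likelihoods,
         pairings_by_block = tibble::as_tibble(pairings_by_block),
         n_blocks = as.integer(n_blocks),
         main_trials_per_block = as.integer(main_trials_per_block),
         run_length = as.integer(run_length),
         prior_only_period = as.integer(prior_only_period),
         sd_mode = sd_mode),
    class = "schedule_config"
  )
  validate_config(cfg)
}

#' Validate a schedule configuration
#'
#' Checks the structural invariants: per-block pairing counts sum to
#' `main_trials_per_block`; all pairings reference known priors/likelihoods;
#' `run_length` is even; exp1/exp2 blocks 1-3 contain no high-likelihood
#' pairings; exp3 contains all pairings in every block.
#'
#' @param config A `schedule_config`.
#' @return `config`, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "schedule_config")) {
    stop("`config` must be a schedule_config", call. = FALSE)
  }
  pb <- config$pairings_by_block
  needed <- c("block", "prior_id", "likelihood_id", "n_trials")
  missing <- setdiff(needed, names(pb))
  if (length(missing)) {
    stop("pairings_by_block lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_priors(config$priors)
  check_likelihoods(config$likelihoods)
  bad_p <- setdiff(pb$prior_id, config$priors$prior_id)
  if (length(bad_p)) {
    stop("pairings_by_block references unknown prior_id: ",
         paste(bad_p, collapse = ", "), call. = FALSE)
  }
  bad_l <- setdiff(pb$likelihood_id, config$likelihoods$likelihood_id)
  if (length(bad_l)) {
    stop("pairings_by_block references unknown likelihood_id: ",
         paste(bad_l, collapse = ", "), call. = FALSE)
  }
  if (config$run_length < 2 || config$run_length %% nrow(config$priors) != 0) {
    stop("run_length must be a positive multiple of the number of priors",
         call. = FALSE)
  }
  if (config$prior_only_period < 1) {
    stop("prior_only_period must be >= 1", call. = FALSE)
  }
  sums <- tapply(pb$n_trials, pb$block, sum)
  if (any(sums != config$main_trials_per_block)) {
    stop("per-block pairing counts must sum to main_trials_per_block (",
         config$main_trials_per_block, "); got ",
         paste(sums, collapse = ", "), call. = FALSE)
  }
  if (config$experiment %in% c("exp1", "exp2")) {
    early_high <- pb$block <= 3 & pb$likelihood_id == "high"
    if (any(early_high)) {
      stop("exp1/exp2 blocks 1-3 must not contain high-likelihood pairings",
           call. = FALSE)
    }
  }
  if (config$experiment == "exp3") {
    full <- tidyr::expand_grid(block = seq_len(config$n_blocks),
                               prior_id = config$priors$prior_id,
                               likelihood_id = config$likelihoods$likelihood_id)
    have <- dplyr::anti_join(full, pb,
                             by = c("block", "prior_id", "likelihood_id"))
    if (nrow(have)) {
      stop("exp3 must contain every prior x likelihood pairing in every block",
           call. = FALSE)
    }
  }
  invisible(config)
}

#' Default experiment configuration
#'
#' Returns the study's parameterization for one of the three experiments:
#' five blocks of 300 main trials; in `exp1`/`exp2`, blocks 1-3 pair the two
#' priors with the low and medium likelihoods only (75 trials per pairing) and
#' the high likelihood joins in blocks 4-5 (50 trials per pairing); in `exp3`
#' all six pairings appear in every block (50 trials each). `exp2` differs from
#' `exp1` only in participant instructions, which is not a schedule property,
#' so the two schedules are identical.
#'
#' @inheritParams schedule_config
#' @return A `schedule_config`.
#' @examples
#' cfg <- default_config("exp1")
#' subset(cfg$pairings_by_block, block == 1)
#' @export
default_config <- function(experiment = c("exp1", "exp2", "exp3"),
                           priors = default_priors(),
                           likelihoods = default_likelihoods(),
                           sd_mode = "population") {
  experiment <- match.arg(experiment)
  pairing_block <- function(blocks, lik_ids, n_each) {
    tidyr::expand_grid(block = blocks,
                       prior_id = priors$prior_id,
                       likelihood_id = lik_ids) |>
      dplyr::mutate(n_trials = n_each)
  }
  pb <- if (experiment %in% c("exp1", "exp2")) {
    dplyr::bind_rows(
      pairing_block(1:3, c("low", "medium"), 75L),
      pairing_block(4:5, c("low", "medium", "high"), 50L)
    )
  } else {
    pairing_block(1:5, c("low", "medium", "high"), 50L)
  }
  schedule_config(experiment = experiment, priors = priors,
                  likelihoods = likelihoods, pairings_by_block = pb,
                  n_blocks = 5L, main_trials_per_block = 300L,
                  run_length = 20L, prior_only_period = 9L, sd_mode = sd_mode)
}

#' Read a schedule configuration from YAML or JSON
#'
#' The file may specify `experiment` alone (defaults are filled in) and
#' override any of: `priors` (list of records with `prior_id`, `mu_p`,
#' `sigma_p`, optionally `color`), `likelihoods` (`likelihood_id`, `sigma_l`,
#' `n_dots`), `blocks` (records with `block`, `prior_id`, `likelihood_id`,
#' `n_trials`), `run_length`, `prior_only_period`, `sd_mode`, `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `schedule_config`; any `seed` key is attached as attribute
#'   `"seed"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$experiment)) {
    stop("config field `experiment` is required", call. = FALSE)
  }
  to_tbl <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x)
    else dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  priors <- if (is.null(raw$priors)) default_priors() else to_tbl(raw$priors)
  likelihoods <- if (is.null(raw$likelihoods)) default_likelihoods()
                 else to_tbl(raw$likelihoods)
  if (!"color" %in% names(priors)) priors$color <- NA_character_
  if (!"n_dots" %in% names(likelihoods)) likelihoods$n_dots <- 8L
  cfg <- if (is.null(raw$blocks)) {
    base <- default_config(raw$experiment, priors = priors,
                           likelihoods = likelihoods)
    if (!is.null(raw$run_length)) base$run_length <- as.integer(raw$run_length)
    if (!is.null(raw$prior_only_period)) {
      base$prior_only_period <- as.integer(raw$prior_only_period)
    }
    if (!is.null(raw$sd_mode)) base$sd_mode <- raw$sd_mode
    validate_config(base)
  } else {
    schedule_config(
      experiment = raw$experiment, priors = priors, likelihoods = likelihoods,
      pairings_by_block = to_tbl(raw$blocks),
      run_length = raw$run_length %||% 20L,
      prior_only_period = raw$prior_only_period %||% 9L,
      sd_mode = raw$sd_mode %||% "population"
    )
  }
  attr(cfg, "seed") <- raw$seed
  cfg
}

#' @export
print.schedule_config <- function(x, ...) {
  cat("<schedule_config>", x$experiment, "\n")
  cat("  blocks:", x$n_blocks, "x", x$main_trials_per_block, "main trials;",
      "run length", x$run_length, "; prior-only every", x$prior_only_period,
      "main trials\n")
  cat("  priors:", paste(sprintf("%s(mu=%g, sd=%g)", x$priors$prior_id,
                                 x$priors$mu_p, x$priors$sigma_p),
                         collapse = ", "), "\n")
  cat("  likelihoods:", paste(sprintf("%s(sd=%g)", x$likelihoods$likelihood_id,
                                      x$likelihoods$sigma_l), collapse = ", "),
      "; n_dots:", x$likelihoods$n_dots[1], "\n")
  cat("  sd_mode:", x$sd_mode, "\n")
  invisible(x)
}
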