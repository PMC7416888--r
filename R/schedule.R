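#' Population-form standard deviation
#'
#' Divide-by-n SD, the default convention for the exact-SD rescaling of dot
#' clouds and the moment correction of run targets (see `sd_mode` in
#' [schedule_config()]).
#'
#' @param x Numeric vector.
#' @return The square root of the mean squared deviation from the mean.
#' @export
population_sd <- function(x) sqrt(mean((x - mean(x))^2))

sd_by_mode <- function(x, sd_mode) {
  if (sd_mode == "population") population_sd(x) else stats::sd(x)
}

#' Moment-corrected target samples for one run
#'
#' Draws `n_targets` Gaussian target locations and applies the affine
#' correction `x' = mu + (x - mean(x)) * sigma / s(x)` so that the returned
#' values have sample mean exactly `mu` and sample SD (under the chosen
#' convention) exactly `sigma`. Over a run scheduled this way an ideal learner
#' accumulating evidence has an exact estimate of the prior's mean and SD.
#' Degenerate draws with zero sample SD are redrawn.
#'
#' @param mu,sigma Prior mean and SD, psw.
#' @param n_targets Number of targets, >= 2.
#' @param sd_mode SD convention, `"population"` or `"sample"`.
#' @return Numeric vector of length `n_targets`.
#' @examples
#' x <- sample_run_targets(35, 1, 10)
#' mean(x)           # exactly 35
#' population_sd(x)  # exactly 1
#' @export
sample_run_targets <- function(mu, sigma, n_targets,
                               sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (n_targets < 2) stop("`n_targets` must be >= 2", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  repeat {
    x <- stats::rnorm(n_targets)
    s <- sd_by_mode(x, sd_mode)
    if (s > 0) break
  }
  mu + (x - mean(x)) * sigma / s
}

#' Generate one dot-cloud stimulus
#'
#' Dot horizontal positions are `n_dots` iid Gaussian draws about `target_x`,
#' rescaled about their sample mean so that their SD equals `sigma_l` exactly
#' while the mean (the centroid, the cue an ideal observer extracts) is
#' preserved. Vertical positions are the fixed symmetric ladder with 1 psw
#' spacing (for 8 dots: -3.5, -2.5, ..., 3.5), assigned to the horizontal
#' values in shuffled order; they carry no information about the target.
#'
#' @param target_x True target location, psw.
#' @param sigma_l Likelihood SD, psw.
#' @param n_dots Even dot count.
#' @inheritParams sample_run_targets
#' @return List with `dot_xs`, `dot_ys` and `centroid` (pre-rescaling sample
#'   mean of the draws, unchanged by the rescaling).
#' @export
generate_dot_cloud <- function(target_x, sigma_l, n_dots = 8L,
                               sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  if (sigma_l <= 0) stop("`sigma_l` must be > 0", call. = FALSE)
  repeat {
    raw <- stats::rnorm(n_dots, mean = target_x, sd = sigma_l)
    s <- sd_by_mode(raw, sd_mode)
    if (s > 0) break
  }
  centroid <- mean(raw)
  dot_xs <- centroid + (raw - centroid) * sigma_l / s
  offsets <- seq_len(n_dots) - (n_dots + 1) / 2
  list(dot_xs = dot_xs, dot_ys = sample(offsets), centroid = centroid)
}

#' Catch rule for the netting task
#'
#' The response is a net of width 1 psw centred on `response_x`; the feedback
#' dot has diameter 0.5 psw. The target is caught when the horizontal overlap
#' between net and feedback dot is at least half the dot's size (0.25 psw),
#' i.e. when `|response_x - target_x| <= 0.5`. One point per catch.
#'
#' @param response_x,target_x Positions, psw (vectorized).
#' @param net_width,dot_diameter Geometry, psw.
#' @return Tibble with logical `caught` and integer `points`.
#' @examples
#' catch_and_score(c(35, 35.5, 35.6), 35)
#' @export
catch_and_score <- function(response_x, target_x,
                            net_width = 1, dot_diameter = 0.5) {
  overlap <- pmin(response_x + net_width / 2, target_x + dot_diameter / 2) -
    pmax(response_x - net_width / 2, target_x - dot_diameter / 2)
  caught <- overlap >= dot_diameter / 2
  tibble::tibble(caught = caught, points = as.integer(caught))
}

# Chunk a shuffled pairing-label vector into per-run groups of `per_run`
# labels; the final group may be shorter (remainder handling: a short final
# run, moment-corrected at its own size).
chunk_labels <- function(labels, per_run) {
  split(labels, ceiling(seq_along(labels) / per_run))
}

build_block_main <- function(config, block) {
  pb <- config$pairings_by_block
  pb <- pb[pb$block == block, , drop = FALSE]
  priors <- config$priors
  per_run <- config$run_length / nrow(priors)

  # Per prior: shuffled likelihood labels chunked into runs, plus
  # moment-corrected targets per run chunk.
  per_prior <- lapply(priors$prior_id, function(pid) {
    rows <- pb[pb$prior_id == pid, , drop = FALSE]
    labels <- rep(rows$likelihood_id, rows$n_trials)
    labels <- sample(labels)
    chunks <- chunk_labels(labels, per_run)
    lapply(chunks, function(liks) {
      mu <- priors$mu_p[priors$prior_id == pid]
      sg <- priors$sigma_p[priors$prior_id == pid]
      targets <- if (length(liks) >= 2) {
        sample_run_targets(mu, sg, length(liks), config$sd_mode)
      } else {
        mu  # a single leftover trial cannot be moment-corrected; pin to mu
      }
      tibble::tibble(prior_id = pid, likelihood_id = liks, target_x = targets)
    })
  })

  n_runs <- max(vapply(per_prior, length, integer(1)))
  runs <- lapply(seq_len(n_runs), function(r) {
    parts <- lapply(per_prior, function(ch) if (r <= length(ch)) ch[[r]] else NULL)
    run <- dplyr::bind_rows(parts)
    run <- run[sample(nrow(run)), , drop = FALSE]  # interleave priors
    run$run_in_block <- r
    run
  })
  dplyr::bind_rows(runs)
}

#' Build a full trial schedule
#'
#' Produces the complete, reproducible trial sequence for one session: main
#' trials grouped into moment-balanced runs (each run holds
#' `run_length / n_priors` trials per prior whose targets match the prior's
#' mean and SD exactly), pairings interleaved by a within-run shuffle, dot
#' clouds generated and rescaled to exact SD, and one prior-only trial inserted
#' after every `prior_only_period` main trials with alternating prior identity
#' (the insertion counter runs across blocks, giving 166 prior-only trials — 83
#' per prior — over the default 1500 main trials). Prior-only targets are plain
#' draws from the prior and carry no dots.
#'
#' @param config A [schedule_config()].
#' @param seed Integer seed; schedules are reproducible from `(config, seed)`.
#' @return A tibble, one row per trial: `experiment`, `block`, `trial_index`
#'   (global), `index_in_block`, `run` (global run index, `NA` for prior-only
#'   rows), `kind` (`"main"`/`"prior_only"`), `prior_id`, `likelihood_id`,
#'   `target_x`, `centroid`, `dot_x_1..dot_x_n`, `dot_y_1..dot_y_n` (dot and
#'   centroid fields `NA` for prior-only rows).
#' @examples
#' sched <- build_schedule(default_config("exp1"), seed = 1)
#' table(sched$kind)
#' @export
build_schedule <- function(config, seed) {
  validate_config(config)
  set.seed(as.integer(seed))
  n_dots <- config$likelihoods$n_dots[1]

  main <- dplyr::bind_rows(lapply(seq_len(config$n_blocks), function(b) {
    out <- build_block_main(config, b)
    out$block <- b
    out
  }))

  # Dot clouds for every main trial.
  sig_l <- config$likelihoods$sigma_l[match(main$likelihood_id,
                                            config$likelihoods$likelihood_id)]
  clouds <- lapply(seq_len(nrow(main)), function(i) {
    generate_dot_cloud(main$target_x[i], sig_l[i], n_dots, config$sd_mode)
  })
  dotx <- do.call(rbind, lapply(clouds, `[[`, "dot_xs"))
  doty <- do.call(rbind, lapply(clouds, `[[`, "dot_ys"))
  colnames(dotx) <- paste0("dot_x_", seq_len(n_dots))
  colnames(doty) <- paste0("dot_y_", seq_len(n_dots))
  main$centroid <- vapply(clouds, `[[`, numeric(1), "centroid")
  main <- dplyr::bind_cols(main, tibble::as_tibble(dotx),
                           tibble::as_tibble(doty))
  main$kind <- "main"

  # Interleave prior-only trials: one after every `prior_only_period` main
  # trials, alternating prior identity across insertions.
  period <- config$prior_only_period
  n_po <- nrow(main) %/% period
  po_prior <- config$priors$prior_id[(seq_len(n_po) - 1) %% nrow(config$priors) + 1]
  po <- tibble::tibble(
    kind = "prior_only",
    prior_id = po_prior,
    likelihood_id = NA_character_,
    target_x = stats::rnorm(
      n_po,
      mean = config$priors$mu_p[match(po_prior, config$priors$prior_id)],
      sd = config$priors$sigma_p[match(po_prior, config$priors$prior_id)]
    ),
    centroid = NA_real_,
    block = main$block[seq_len(n_po) * period],
    run_in_block = NA_integer_
  )

  # Position keys: main trial j sits at j + (#insertions before it).
  main_pos <- seq_len(nrow(main)) + (seq_len(nrow(main)) - 1) %/% period
  po_pos <- seq_len(n_po) * period + seq_len(n_po)
  sched <- dplyr::bind_rows(main, po)
  sched <- sched[order(c(main_pos, po_pos)), , drop = FALSE]

  sched$experiment <- config$experiment
  sched$trial_index <- seq_len(nrow(sched))
  sched <- sched |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(index_in_block = dplyr::row_number()) |>
    dplyr::ungroup()
  runs_per_block <- ceiling(config$main_trials_per_block / config$run_length)
  sched$run <- ifelse(is.na(sched$run_in_block), NA_integer_,
                      (sched$block - 1L) * runs_per_block + sched$run_in_block)
  sched$run_in_block <- NULL

  dplyr::relocate(sched, "experiment", "block", "trial_index",
                  "index_in_block", "run", "kind", "prior_id", "likelihood_id",
                  "target_x", "centroid")
}
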