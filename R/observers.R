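#' Closed-form weights on the sensory cue
#'
#' Three reliability-weighting rules for the weight placed on the dot-cloud
#' centroid relative to the prior mean, each the precision-weighting
#' `w = (1/var_cue) / (1/var_cue + 1/sigma_p^2)` with a different cue variance:
#'
#' * `optimal_weight()` — the ideal observer with perfect knowledge of the
#'   externally imposed cue variance: `var_cue = sigma_l^2 / n`.
#' * `internal_noise_weight()` — an observer weighting only by its own internal
#'   variability in using the cue: `var_cue = sigma_li^2`.
#' * `overall_variability_weight()` — an observer accounting for both:
#'   `var_cue = sigma_l^2 / n + sigma_li^2`.
#'
#' All arguments are vectorized and SDs are in percent screen width.
#'
#' @param sigma_l SD of the dot-generating distribution, psw (> 0).
#' @param n_dots Number of dots averaged (>= 1).
#' @param sigma_p Prior SD, psw (> 0).
#' @param sigma_li Internal centroid-estimation noise SD, psw (>= 0).
#' @return Weight(s) in \[0, 1\].
#' @examples
#' optimal_weight(3, 8, 1)              # ~ 0.47
#' internal_noise_weight(2, 2.5)        # ~ 0.61
#' overall_variability_weight(3, 8, 0, 1) == optimal_weight(3, 8, 1)
#' @export
optimal_weight <- function(sigma_l, n_dots, sigma_p) {
  if (any(sigma_l <= 0) || any(sigma_p <= 0)) {
    stop("`sigma_l` and `sigma_p` must be > 0", call. = FALSE)
  }
  if (any(n_dots < 1)) stop("`n_dots` must be >= 1", call. = FALSE)
  prec_cue <- n_dots / sigma_l^2
  prec_cue / (prec_cue + 1 / sigma_p^2)
}

#' @rdname optimal_weight
#' @export
internal_noise_weight <- function(sigma_li, sigma_p) {
  if (any(sigma_p <= 0)) stop("`sigma_p` must be > 0", call. = FALSE)
  if (any(sigma_li < 0)) stop("`sigma_li` must be >= 0", call. = FALSE)
  sigma_p^2 / (sigma_li^2 + sigma_p^2)
}

#' @rdname optimal_weight
#' @export
overall_variability_weight <- function(sigma_l, n_dots, sigma_li, sigma_p) {
  if (any(sigma_l <= 0) || any(sigma_p <= 0)) {
    stop("`sigma_l` and `sigma_p` must be > 0", call. = FALSE)
  }
  if (any(sigma_li < 0)) stop("`sigma_li` must be >= 0", call. = FALSE)
  var_lo <- sigma_l^2 / n_dots + sigma_li^2
  (1 / var_lo) / (1 / var_lo + 1 / sigma_p^2)
}

#' Candidate centroid estimators of a dot cloud
#'
#' The estimates an observer could plausibly take from the cloud: the
#' arithmetic mean (the sufficient statistic), the median, the mid-range
#' `(min + max) / 2`, and a robust average. The robust average is an
#' iteratively trimmed mean: dots further than `trim_k` sample SDs from the
#' current mean are dropped and the mean recomputed until the retained set is
#' stable; on an outlier-free cloud nothing is trimmed and it equals the mean.
#'
#' @param dot_xs Numeric vector of >= 2 dot positions.
#' @param trim_k Trim threshold in sample SDs for the robust average.
#' @return Named numeric vector `mean`, `median`, `midrange`, `robust_average`.
#' @examples
#' centroid_estimators(c(0, 0, 0, 0, 0, 0, 0, 8))
#' @export
centroid_estimators <- function(dot_xs, trim_k = 2) {
  if (length(dot_xs) < 2) stop("need at least 2 dots", call. = FALSE)
  c(mean = mean(dot_xs),
    median = stats::median(dot_xs),
    midrange = (min(dot_xs) + max(dot_xs)) / 2,
    robust_average = robust_average(dot_xs, trim_k))
}

#' @rdname centroid_estimators
#' @export
robust_average <- function(dot_xs, trim_k = 2) {
  keep <- dot_xs
  repeat {
    m <- mean(keep)
    s <- stats::sd(keep)
    if (!is.finite(s) || s == 0) return(m)
    new <- keep[abs(keep - m) <= trim_k * s]
    if (length(new) < 2 || length(new) == length(keep)) {
      return(mean(if (length(new) >= 2) new else keep))
    }
    keep <- new
  }
}

#' Observer parameters
#'
#' Bundles a response strategy with its per-subject noise and learning
#' parameters. Strategies:
#'
#' * `ideal_bayes` — weights by [optimal_weight()] using the *true* prior and
#'   likelihood parameters (normative reference).
#' * `bayes_transfer` — weights using its *learned* prior belief and, by
#'   default (`transfer_rule = "optimal"`), the cue SD read off the displayed
#'   cloud; immediately generalizes to a never-trained likelihood level with no
#'   feedback-driven learning. `transfer_rule = "internal"` weights by internal
#'   noise instead.
#' * `internal_noise` — weights only by its internal variability:
#'   [internal_noise_weight()] with the learned prior SD.
#' * `lookup_table` — keeps one weight per experienced (prior, likelihood)
#'   pairing, initialized at 1 (pure cue use) and updated by the delta rule
#'   `w <- w - learn_rate * (response - target) * (perceived_centroid -
#'   believed_mean)`, clipped to \[0, 1\]. Queried on a never-seen pairing it
#'   falls back to the weight of the experienced likelihood with the nearest
#'   `sigma_l` under the same prior — the mechanism that produces "no transfer".
#' * `fixed_weight` — a fixed weight per likelihood condition (or a scalar),
#'   blended with the *true* prior mean; used for parameter-recovery checks.
#'
#' `ideal_bayes` and `fixed_weight` use true prior parameters; the other
#' strategies maintain a running belief (mean and SD) about each prior, updated
#' from trial feedback, initialized at `prior_init_mean`/`prior_init_sd` before
#' any feedback.
#'
#' @param strategy Strategy label (see above).
#' @param sigma_li Internal centroid-estimation noise SD, psw: a scalar or a
#'   vector named by likelihood condition.
#' @param sigma_m Motor noise SD, psw.
#' @param learn_rate Delta-rule step size for `lookup_table`. The update
#'   multiplies psw-scale quantities, so its effective per-trial convergence
#'   rate is `learn_rate * Var(perceived_centroid - believed_mean)`; the
#'   default 2e-5 makes feedback-driven change slow relative to one block, the
#'   rote-learning regime the strategy represents.
#' @param fixed_w Weight(s) for `fixed_weight`: scalar or named by likelihood.
#' @param transfer_rule `"optimal"` or `"internal"` (for `bayes_transfer`).
#' @param prior_init_mean,prior_init_sd Belief about a prior before any
#'   feedback, psw (screen centre, vague SD).
#' @param prior_only_mode On prior-only trials the observer either samples its
#'   response from the believed prior (`"sample"`, default — response SD then
#'   tracks the learned prior SD) or responds at the believed mean (`"mean"`).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(strategy = c("ideal_bayes", "bayes_transfer",
                                         "internal_noise", "lookup_table",
                                         "fixed_weight"),
                            sigma_li = 0, sigma_m = 0,
                            learn_rate = 2e-5, fixed_w = NULL,
                            transfer_rule = c("optimal", "internal"),
                            prior_init_mean = 50, prior_init_sd = 5,
                            prior_only_mode = c("sample", "mean")) {
  strategy <- match.arg(strategy)
  transfer_rule <- match.arg(transfer_rule)
  prior_only_mode <- match.arg(prior_only_mode)
  if (any(sigma_li < 0)) stop("`sigma_li` must be >= 0", call. = FALSE)
  if (sigma_m < 0) stop("`sigma_m` must be >= 0", call. = FALSE)
  if (!is.null(fixed_w) && any(fixed_w < 0 | fixed_w > 1)) {
    stop("`fixed_w` must lie in [0, 1]", call. = FALSE)
  }
  if (strategy == "fixed_weight" && is.null(fixed_w)) {
    stop("strategy `fixed_weight` requires `fixed_w`", call. = FALSE)
  }
  structure(
    list(strategy = strategy, sigma_li = sigma_li, sigma_m = sigma_m,
         learn_rate = learn_rate, fixed_w = fixed_w,
         transfer_rule = transfer_rule,
         prior_init_mean = prior_init_mean, prior_init_sd = prior_init_sd,
         prior_only_mode = prior_only_mode),
    class = "observer_params"
  )
}

sigma_li_for <- function(observer, likelihood_id) {
  s <- observer$sigma_li
  if (length(s) == 1 && is.null(names(s))) return(unname(s))
  if (!likelihood_id %in% names(s)) {
    stop("no sigma_li entry for likelihood `", likelihood_id, "`",
         call. = FALSE)
  }
  unname(s[[likelihood_id]])
}

fixed_w_for <- function(observer, likelihood_id) {
  w <- observer$fixed_w
  if (length(w) == 1 && is.null(names(w))) return(unname(w))
  if (!likelihood_id %in% names(w)) {
    stop("no fixed_w entry for likelihood `", likelihood_id, "`",
         call. = FALSE)
  }
  unname(w[[likelihood_id]])
}

# Fresh mutable observer state (belief per prior + look-up table).
new_observer_state <- function(observer, priors) {
  list(
    belief = stats::setNames(
      lapply(priors$prior_id, function(p) list(n = 0L, mean = NA_real_,
                                               m2 = 0)),
      priors$prior_id),
    lookup = list()  # named "prior|likelihood" -> weight
  )
}

belief_mean <- function(state, prior_id, observer) {
  b <- state$belief[[prior_id]]
  if (b$n >= 1) b$mean else observer$prior_init_mean
}

belief_sd <- function(state, prior_id, observer) {
  b <- state$belief[[prior_id]]
  if (b$n >= 2) sqrt(b$m2 / (b$n - 1)) else observer$prior_init_sd
}

update_belief <- function(state, prior_id, x) {
  b <- state$belief[[prior_id]]
  b$n <- b$n + 1L
  d <- x - (if (b$n == 1L) 0 else b$mean)
  if (b$n == 1L) {
    b$mean <- x
  } else {
    b$mean <- b$mean + d / b$n
    b$m2 <- b$m2 + d * (x - b$mean)
  }
  state$belief[[prior_id]] <- b
  state
}

lookup_key <- function(prior_id, likelihood_id) {
  paste(prior_id, likelihood_id, sep = "|")
}

lookup_weight <- function(state, prior_id, likelihood_id, likelihoods) {
  key <- lookup_key(prior_id, likelihood_id)
  if (!is.null(state$lookup[[key]])) return(state$lookup[[key]])
  # Never-seen pairing: fall back to the experienced likelihood (same prior)
  # with the nearest sigma_l; with no experience at all, start at 1.
  seen <- names(state$lookup)
  if (is.null(seen)) return(1)
  seen <- seen[startsWith(seen, paste0(prior_id, "|"))]
  if (!length(seen)) return(1)
  seen_lik <- sub(".*\\|", "", seen)
  sig <- likelihoods$sigma_l[match(seen_lik, likelihoods$likelihood_id)]
  target_sig <- likelihoods$sigma_l[likelihoods$likelihood_id == likelihood_id]
  state$lookup[[seen[which.min(abs(sig - target_sig))]]]
}

#' Simulate one trial response
#'
#' The response model behind the weight-regression analysis: the observer
#' perceives the centroid with internal noise, blends it with its prior mean
#' by a strategy-dependent weight, and adds motor noise:
#' `response = w * (centroid + N(0, sigma_li)) + (1 - w) * prior_mean +
#' N(0, sigma_m)`. On prior-only trials the response comes from the believed
#' prior alone (see `prior_only_mode` in [observer_params()]). After feedback
#' (the true target), learning strategies update their running prior belief
#' and the look-up table its condition weight.
#'
#' Uses the current RNG stream; seed control belongs to the session/cohort
#' level ([generate_cohort()]).
#'
#' @param observer An [observer_params()].
#' @param state Observer state from `new_observer_state()` (or `NULL` to start
#'   fresh).
#' @param trial A one-row portion of a [build_schedule()] tibble (fields
#'   `kind`, `prior_id`, `likelihood_id`, `target_x`, `centroid`, dot columns).
#' @param priors,likelihoods Condition tables.
#' @return List with `response_x`, `w` (weight used, `NA` on prior-only
#'   trials) and the updated `state`.
#' @export
simulate_response <- function(observer, state, trial, priors = default_priors(),
                              likelihoods = default_likelihoods()) {
  if (is.null(state)) state <- new_observer_state(observer, priors)
  n_dots <- likelihoods$n_dots[1]
  dot_cols <- paste0("dot_x_", seq_len(n_dots))
  cloud_sd <- if (trial$kind == "main" && all(dot_cols %in% names(trial))) {
    population_sd(as.numeric(trial[1, dot_cols]))
  } else {
    NA_real_
  }
  res <- simulate_one(
    observer, state,
    kind = trial$kind, prior_id = trial$prior_id,
    likelihood_id = trial$likelihood_id, target_x = trial$target_x,
    centroid = trial$centroid, cloud_sd = cloud_sd,
    priors = priors, likelihoods = likelihoods
  )
  res
}

# Core per-trial kernel shared by simulate_response() and session loops.
simulate_one <- function(observer, state, kind, prior_id, likelihood_id,
                         target_x, centroid, cloud_sd, priors, likelihoods) {
  uses_belief <- observer$strategy %in%
    c("bayes_transfer", "internal_noise", "lookup_table")
  true_mu <- priors$mu_p[priors$prior_id == prior_id]
  true_sd <- priors$sigma_p[priors$prior_id == prior_id]

  if (kind == "prior_only") {
    if (uses_belief) {
      bm <- belief_mean(state, prior_id, observer)
      bs <- belief_sd(state, prior_id, observer)
    } else {
      bm <- true_mu
      bs <- true_sd
    }
    centre <- if (observer$prior_only_mode == "sample") {
      stats::rnorm(1, bm, bs)
    } else {
      bm
    }
    response <- centre + stats::rnorm(1, 0, observer$sigma_m)
    if (uses_belief) state <- update_belief(state, prior_id, target_x)
    return(list(response_x = response, w = NA_real_, state = state))
  }

  s_li <- sigma_li_for(observer, likelihood_id)
  pc <- centroid + stats::rnorm(1, 0, s_li)
  bm <- if (uses_belief) belief_mean(state, prior_id, observer) else true_mu

  w <- switch(
    observer$strategy,
    ideal_bayes = {
      s_l <- likelihoods$sigma_l[likelihoods$likelihood_id == likelihood_id]
      optimal_weight(s_l, likelihoods$n_dots[1], true_sd)
    },
    fixed_weight = fixed_w_for(observer, likelihood_id),
    bayes_transfer = {
      bs <- belief_sd(state, prior_id, observer)
      if (observer$transfer_rule == "optimal") {
        optimal_weight(cloud_sd, likelihoods$n_dots[1], bs)
      } else {
        internal_noise_weight(s_li, bs)
      }
    },
    internal_noise = {
      bs <- belief_sd(state, prior_id, observer)
      internal_noise_weight(s_li, bs)
    },
    lookup_table = lookup_weight(state, prior_id, likelihood_id, likelihoods)
  )

  response <- w * pc + (1 - w) * bm + stats::rnorm(1, 0, observer$sigma_m)

  if (uses_belief) {
    if (observer$strategy == "lookup_table") {
      err <- response - target_x
      w_new <- w - observer$learn_rate * err * (pc - bm)
      state$lookup[[lookup_key(prior_id, likelihood_id)]] <-
        min(1, max(0, w_new))
    }
    state <- update_belief(state, prior_id, target_x)
  }
  list(response_x = response, w = w, state = state)
}

#' Expected catch probability of a weighting strategy
#'
#' For an observer blending the cue and the true prior mean with weight `w`,
#' the response error is Gaussian with variance
#' `w^2 sigma_l^2 / n + (1 - w)^2 sigma_p^2 + sigma_m^2`, and a catch occurs
#' when the error lies within `half_window` (0.5 psw under the default catch
#' geometry). The expected catch rate is `2 * pnorm(half_window / sigma_err)
#' - 1`; with `sigma_m` independent of `w` it is maximized at
#' [optimal_weight()] — the sense in which deviating from optimal weights can
#' cost little reward ("optimally lazy" behaviour is ruled in or out by how
#' flat this curve is near its peak).
#'
#' @param w Weight on the cue, in \[0, 1\].
#' @inheritParams optimal_weight
#' @param sigma_m Motor noise SD, psw.
#' @param half_window Half-width of the catch window, psw (> 0).
#' @return Catch probability in (0, 1\].
#' @examples
#' w_star <- optimal_weight(6, 8, 1)
#' expected_catch_rate(w_star, 6, 8, 1) > expected_catch_rate(0.99, 6, 8, 1)
#' @export
expected_catch_rate <- function(w, sigma_l, n_dots, sigma_p, sigma_m = 0,
                                half_window = 0.5) {
  if (any(w < 0 | w > 1)) stop("`w` must lie in [0, 1]", call. = FALSE)
  if (half_window <= 0) stop("`half_window` must be > 0", call. = FALSE)
  var_err <- w^2 * sigma_l^2 / n_dots + (1 - w)^2 * sigma_p^2 + sigma_m^2
  ifelse(var_err == 0, 1, 2 * stats::pnorm(half_window / sqrt(var_err)) - 1)
}
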