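make_log <- function(abs_errors, prior_id = "narrow",
                     likelihood_id = "medium", subject_id = "S01") {
  tibble::tibble(
    subject_id = subject_id, kind = "main", prior_id = prior_id,
    likelihood_id = likelihood_id, block = 1L,
    trial_index = seq_along(abs_errors),
    target_x = 35, centroid = 35, response_x = 35 + abs_errors,
    abs_error = abs_errors
  )
}

test_that("outlier exclusion drops exactly the trials above the pairing 99th percentile", {
  log <- make_log(c(rep(0.5, 198), 10, 12))
  res <- exclude_outliers(log)
  expect_equal(res$pairing_report$n_dropped, 2)
  expect_equal(nrow(res$log), 198)
  expect_true(all(res$log$abs_error <= res$pairing_report$threshold))
  expect_equal(res$subject_report$max_dropped_per_pairing, 2)

  # degenerate distribution: nothing strictly above the percentile
  flat <- exclude_outliers(make_log(rep(1, 100)))
  expect_equal(flat$pairing_report$n_dropped, 0)
  expect_equal(nrow(flat$log), 100)
})

test_that("outlier exclusion never removes more than 1% of a pairing", {
  set.seed(17)
  log <- dplyr::bind_rows(
    make_log(rexp(400), likelihood_id = "low"),
    make_log(rexp(250), likelihood_id = "medium"),
    make_log(rexp(103), likelihood_id = "high")
  )
  res <- exclude_outliers(log)
  expect_true(all(res$pairing_report$n_dropped <=
                    ceiling(0.01 * res$pairing_report$n)))
  expect_true(all(res$pairing_report$n_dropped >= 0))
})

test_that("weight regression is exact on noise-free responses", {
  cfg <- mini_config()
  sched <- build_schedule(cfg, seed = 51)
  obs <- observer_params("fixed_weight", fixed_w = 0.7, sigma_li = 0,
                         sigma_m = 0)
  sess <- simulate_session(obs, sched, seed = 52)
  w <- fit_weights(sess, grain = "pooled", min_trials = 5)
  expect_equal(w$slope, rep(0.7, nrow(w)), tolerance = 1e-12)
  mu <- cfg$priors$mu_p[match(w$prior_id, cfg$priors$prior_id)]
  expect_equal(w$intercept, 0.3 * mu, tolerance = 1e-12)
  expect_true(all(w$flag == "ok"))

  # responses regressed on themselves have slope one
  ident <- sess[sess$kind == "main", ]
  ident$response_x <- ident$centroid
  wi <- fit_weights(ident, grain = "pooled", min_trials = 5)
  expect_equal(wi$slope, rep(1, nrow(wi)), tolerance = 1e-12)
})

test_that("under-filled and singular regression cells are flagged, not fitted", {
  log <- make_log(rep(0.1, 5))
  w <- fit_weights(log, grain = "pooled", min_trials = 10)
  expect_false(w$fitted)
  expect_equal(w$flag, "too_few_trials")

  const <- make_log(rep(0.1, 20))  # centroid constant at 35
  w2 <- fit_weights(const, grain = "pooled", min_trials = 10)
  expect_equal(w2$flag, "singular")
  expect_true(is.na(w2$slope))
})

test_that("estimator R^2 identifies the estimate responses were built from", {
  cfg <- mini_config()
  sched <- build_schedule(cfg, seed = 61)
  main <- sched[sched$kind == "main", ]
  dots <- as.matrix(main[, paste0("dot_x_", 1:8)])
  set.seed(62)
  noise <- rnorm(nrow(main), 0, 0.2)

  from_mean <- main
  from_mean$response_x <- rowMeans(dots) + noise
  r2_mean <- estimator_r2(from_mean)
  expect_equal(attr(r2_mean, "best"), "mean")

  from_mid <- main
  from_mid$response_x <- (apply(dots, 1, min) + apply(dots, 1, max)) / 2 +
    noise
  r2_mid <- estimator_r2(from_mid)
  expect_equal(attr(r2_mid, "best"), "midrange")

  # response regressed on the very estimate it equals gives R^2 of one
  exact <- main
  exact$response_x <- rowMeans(dots)
  expect_equal(estimator_r2(exact)$r2[1], 1, tolerance = 1e-12)

  expect_error(estimator_r2(main[, !grepl("^dot_x_", names(main))]),
               "dot position")
})

test_that("prior-only summaries expose learned-prior bias and spread", {
  po <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:4),
                           prior_id = c("narrow", "wide"),
                           trial = 1:20)
  po$kind <- "prior_only"
  # a responder stuck at the initial belief of 50 psw, zero variance
  po$response_x <- 50
  res <- prior_only_summary(po)
  expect_equal(res$summary$mean_bias[res$summary$prior_id == "narrow"],
               50 - 35)
  expect_equal(res$summary$mean_bias[res$summary$prior_id == "wide"],
               50 - 70)
  expect_true(all(res$by_subject$sd_response == 0))
  expect_equal(res$summary$true_sigma_p, c(1, 2.5))

  expect_warning(prior_only_summary(po[po$prior_id == "narrow", ]),
                 "omitted")
  expect_error(prior_only_summary(po[0, ]), "no prior-only")
})

test_that("internal-noise estimation needs enough trials and handles zero noise", {
  ctl <- generate_control_session(20, sigma_li = 0, sigma_m = 0, seed = 71)
  est <- estimate_internal_noise(ctl)
  expect_equal(est$sigma_li_hat, rep(0, 3))
  expect_error(estimate_internal_noise(ctl[1:2, ]), "at least 3")
  expect_error(estimate_internal_noise(ctl[, "target_x"]), "centroid")
})

test_that("model predictions respect the zero-internal-noise limits", {
  sli0 <- tibble::tibble(subject_id = "S01",
                         likelihood_id = c("low", "medium", "high"),
                         sigma_li_hat = 0)
  pred0 <- model_predictions(sli0)
  expect_equal(pred0$w_internal, rep(1, 6))
  expect_equal(pred0$w_overall, pred0$w_external)

  sli <- dplyr::mutate(sli0, sigma_li_hat = c(0.5, 1.3, 2.5))
  pred <- model_predictions(sli)
  expect_true(all(pred$w_overall < pred$w_external))
  expect_warning(model_predictions(NULL), "sigma_li")
})

test_that("model MSE is zero at equality and shifts quadratically", {
  sli <- tibble::tibble(subject_id = "S01",
                        likelihood_id = c("low", "medium", "high"),
                        sigma_li_hat = c(0.5, 1.3, 2.5))
  pred <- model_predictions(sli)
  w <- tibble::tibble(subject_id = pred$subject_id,
                      prior_id = pred$prior_id,
                      likelihood_id = pred$likelihood_id,
                      block = 5L, n_trials = 50L,
                      slope = pred$w_internal, intercept = 0, r2 = 1,
                      fitted = TRUE, flag = "ok")
  mse <- model_mse(w, pred)
  expect_equal(mse$mse[mse$model == "internal"], 0)
  expect_equal(mse$model[1], "internal")  # ranked ascending

  w_shift <- dplyr::mutate(w, slope = slope + 0.1)
  mse_shift <- model_mse(w_shift, pred)
  expect_equal(mse_shift$mse[mse_shift$model == "internal"], 0.01,
               tolerance = 1e-12)

  expect_error(model_mse(w[0, ], pred), "no matched")
})

test_that("transfer contrast is null for condition-independent weights", {
  w <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:6),
                          prior_id = c("narrow", "wide"),
                          likelihood_id = c("low", "medium", "high"),
                          block = 4:5)
  w$n_trials <- 50L
  w$slope <- 0.6
  w$intercept <- 0
  w$r2 <- 0.9
  w$fitted <- TRUE
  w$flag <- "ok"
  tr <- transfer_contrast(w, n_boot = 200)
  expect_equal(tr$first_high_block, 4L)
  expect_equal(tr$immediate_gap$mean, 0)
  expect_equal(tr$exposure_slope$mean, 0)
  expect_equal(tr$immediate_gap$ci, c(0, 0))

  expect_error(transfer_contrast(w[w$likelihood_id != "high", ]),
               "high-likelihood")
  expect_error(transfer_contrast(dplyr::select(w, -block)), "block")
})
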