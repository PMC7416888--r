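test_that("closed-form weights match hand arithmetic and their limits", {
  # sigma_l^2 / n == sigma_p^2 -> equal reliabilities -> 0.5
  expect_equal(optimal_weight(sqrt(8), 8, 1), 0.5)
  # flat prior -> all weight on the cue
  expect_gt(optimal_weight(3, 8, 1e6), 1 - 1e-9)
  expect_equal(optimal_weight(3, 8, 1), (8 / 9) / (8 / 9 + 1))

  expect_equal(internal_noise_weight(0, 2.5), 1)
  expect_equal(internal_noise_weight(2.5, 2.5), 0.5)
  expect_equal(internal_noise_weight(2, 2.5), 6.25 / 10.25)

  # overall-variability model: cue variance 3^2/8 + 1 = 2.125
  expect_equal(overall_variability_weight(3, 8, 1, 1),
               (1 / 2.125) / (1 / 2.125 + 1))
  # noiseless-observer limit reduces to the ideal weight
  expect_equal(overall_variability_weight(3, 8, 0, 1), optimal_weight(3, 8, 1))

  expect_error(optimal_weight(-1, 8, 1), "> 0")
  expect_error(internal_noise_weight(1, 0), "> 0")
})

test_that("weight formulas are monotone in cue noise and prior SD", {
  sp <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(optimal_weight(3, 8, sp)) > 0))
  expect_true(all(diff(internal_noise_weight(1, sp)) > 0))
  expect_true(all(diff(overall_variability_weight(3, 8, 1, sp)) > 0))

  sl <- seq(0.5, 8, by = 0.5)
  expect_true(all(diff(optimal_weight(sl, 8, 1)) < 0))
  expect_true(all(diff(overall_variability_weight(sl, 8, 1, 1)) < 0))
  sli <- seq(0, 4, by = 0.25)
  expect_true(all(diff(internal_noise_weight(sli, 1)) < 0))

  # any internal noise pulls the overall weight strictly below ideal
  expect_true(all(overall_variability_weight(3, 8, sli[-1], 1) <
                    optimal_weight(3, 8, 1)))
})

test_that("all three weight formulas agree with the grid-posterior oracle", {
  grid <- paper_sigma_grid()
  for (i in seq_len(nrow(grid))) {
    sp <- grid$sigma_p[i]
    sl <- grid$sigma_l[i]
    sli <- 1.2
    expect_equal(optimal_weight(sl, 8, sp),
                 grid_posterior_weight(sl / sqrt(8), sp), tolerance = 1e-6)
    expect_equal(internal_noise_weight(sli, sp),
                 grid_posterior_weight(sli, sp), tolerance = 1e-6)
    expect_equal(overall_variability_weight(sl, 8, sli, sp),
                 grid_posterior_weight(sqrt(sl^2 / 8 + sli^2), sp),
                 tolerance = 1e-6)
  }
})

test_that("centroid estimators behave on canonical clouds", {
  est <- centroid_estimators(c(0, 0, 0, 0, 0, 0, 0, 8))
  expect_equal(unname(est["mean"]), 1)
  expect_equal(unname(est["median"]), 0)
  expect_equal(unname(est["midrange"]), 4)
  expect_equal(unname(est["robust_average"]), 0)  # the outlier is trimmed

  sym <- 35 + c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  expect_true(all(abs(centroid_estimators(sym) - 35) < 1e-12))

  # outlier-free cloud: nothing trimmed, robust average equals the mean
  set.seed(4)
  x <- rnorm(8)
  x <- x[abs(x - mean(x)) < 2 * sd(x)]
  expect_equal(robust_average(x), mean(x))

  expect_error(centroid_estimators(1), "at least 2")
})

test_that("simulate_response blends cue and prior deterministically", {
  obs <- observer_params("fixed_weight", fixed_w = 0.7, sigma_li = 0,
                         sigma_m = 0)
  trial <- tibble::tibble(kind = "main", prior_id = "narrow",
                          likelihood_id = "medium", target_x = 36,
                          centroid = 40)
  res <- simulate_response(obs, NULL, trial)
  expect_equal(res$response_x, 0.7 * 40 + 0.3 * 35)  # 38.5
  expect_equal(res$w, 0.7)
})

test_that("noiseless ideal observer regression recovers the ideal weight", {
  cfg <- mini_config()
  sched <- build_schedule(cfg, seed = 5)
  obs <- observer_params("ideal_bayes", sigma_li = 0, sigma_m = 0)
  sess <- simulate_session(obs, sched, seed = 6)
  w <- fit_weights(sess, grain = "pooled", min_trials = 5)
  expected <- optimal_weight(
    cfg$likelihoods$sigma_l[match(w$likelihood_id,
                                  cfg$likelihoods$likelihood_id)],
    8,
    cfg$priors$sigma_p[match(w$prior_id, cfg$priors$prior_id)]
  )
  expect_equal(w$slope, expected, tolerance = 1e-9)
})

test_that("look-up observers fall back to the nearest trained likelihood", {
  obs <- observer_params("lookup_table", sigma_li = 0, sigma_m = 0,
                         learn_rate = 0.01)
  state <- NULL
  # train the medium pairing a little so its weight moves off 1
  set.seed(8)
  for (i in 1:30) {
    trial <- tibble::tibble(kind = "main", prior_id = "narrow",
                            likelihood_id = "medium",
                            target_x = rnorm(1, 35, 1),
                            centroid = rnorm(1, 35, 2))
    res <- simulate_response(obs, state, trial)
    state <- res$state
  }
  w_medium <- state$lookup[["narrow|medium"]]
  expect_lt(w_medium, 1)

  # first-ever high-variance trial: weight equals the trained medium weight
  high_trial <- tibble::tibble(kind = "main", prior_id = "narrow",
                               likelihood_id = "high", target_x = 35,
                               centroid = 41)
  res <- simulate_response(obs, state, high_trial)
  expect_equal(res$w, w_medium)

  # an untrained prior starts from pure cue use
  res2 <- simulate_response(obs, state,
                            tibble::tibble(kind = "main", prior_id = "wide",
                                           likelihood_id = "high",
                                           target_x = 70, centroid = 72))
  expect_equal(res2$w, 1)
})

test_that("expected catch rate has the right limits and peaks at the ideal weight", {
  expect_equal(expected_catch_rate(0.5, 1e-6, 8, 1e-6), 1, tolerance = 1e-9)
  expect_error(expected_catch_rate(1.2, 3, 8, 1), "\\[0, 1\\]")
  expect_error(expected_catch_rate(0.5, 3, 8, 1, half_window = 0), "> 0")

  for (sl in c(3, 6)) for (sp in c(1, 2.5)) {
    w_star <- optimal_weight(sl, 8, sp)
    ws <- seq(0, 1, by = 0.01)
    rates <- expected_catch_rate(ws, sl, 8, sp)
    expect_equal(ws[which.max(rates)], w_star, tolerance = 0.011)
    expect_true(all(expected_catch_rate(w_star, sl, 8, sp) >= rates))
  }

  # near-pure cue use on high-variance trials costs catch rate
  expect_lt(expected_catch_rate(0.99, 6, 8, 1),
            expected_catch_rate(optimal_weight(6, 8, 1), 6, 8, 1))
})
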