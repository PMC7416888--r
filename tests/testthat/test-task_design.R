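test_that("default configurations encode the published block structure", {
  cfg1 <- default_config("exp1")
  pb1 <- cfg1$pairings_by_block

  early <- pb1[pb1$block <= 3, ]
  expect_setequal(unique(early$likelihood_id), c("low", "medium"))
  expect_true(all(early$n_trials == 75))
  late <- pb1[pb1$block >= 4, ]
  expect_setequal(unique(late$likelihood_id), c("low", "medium", "high"))
  expect_true(all(late$n_trials == 50))
  expect_true(all(tapply(pb1$n_trials, pb1$block, sum) == 300))

  # exp2 differs only in instructions, not in schedule
  cfg2 <- default_config("exp2")
  expect_identical(cfg2$pairings_by_block, pb1)
  expect_identical(cfg2$priors, cfg1$priors)

  cfg3 <- default_config("exp3")
  pb3 <- cfg3$pairings_by_block
  expect_true(all(pb3$n_trials == 50))
  expect_equal(nrow(pb3), 5 * 6)

  expect_error(default_config("exp4"), "arg")
})

test_that("config validation names the violated invariant", {
  cfg <- default_config("exp1")
  bad <- cfg
  bad$pairings_by_block$n_trials[1] <- 80L
  expect_error(validate_config(bad), "sum to main_trials_per_block")

  bad <- cfg
  bad$pairings_by_block$prior_id[1] <- "mystery"
  expect_error(validate_config(bad), "unknown prior_id")

  bad <- cfg
  bad$pairings_by_block$likelihood_id[1] <- "high"
  expect_error(validate_config(bad), "blocks 1-3")

  expect_error(prior_spec("narrow", 35, -1), "sigma_p")
  expect_error(likelihood_spec("low", 0), "sigma_l")
  expect_error(likelihood_spec("low", 1, n_dots = 7), "even")
})

test_that("run targets are moment-corrected exactly, independent of seed", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- sample_run_targets(35, 1, 10)
    expect_equal(mean(x), 35, tolerance = 1e-12)
    expect_equal(population_sd(x), 1, tolerance = 1e-12)
  }
  set.seed(1)
  y <- sample_run_targets(70, 2.5, 10, sd_mode = "sample")
  expect_equal(mean(y), 70, tolerance = 1e-12)
  expect_equal(sd(y), 2.5, tolerance = 1e-12)

  set.seed(2)
  a <- sample_run_targets(35, 1, 10)
  set.seed(3)
  b <- sample_run_targets(35, 1, 10)
  expect_false(identical(a, b))  # different orderings, same moments

  expect_error(sample_run_targets(35, 1, 1), "n_targets")
  expect_error(sample_run_targets(35, 0, 10), "sigma")
})

test_that("dot clouds have exact SD, preserved centroid and the fixed ladder", {
  set.seed(7)
  for (sig in c(0.6, 3, 6)) {
    cl <- generate_dot_cloud(35, sig, 8)
    expect_equal(population_sd(cl$dot_xs), sig, tolerance = 1e-12)
    expect_equal(mean(cl$dot_xs), cl$centroid, tolerance = 1e-12)
    expect_setequal(cl$dot_ys, c(-3.5, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, 3.5))
  }
  cl6 <- generate_dot_cloud(50, 2, 6)
  expect_setequal(cl6$dot_ys, c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))
  expect_error(generate_dot_cloud(50, 0), "sigma_l")
})

test_that("centroid scatter about the target matches sigma_l / sqrt(n)", {
  set.seed(11)
  dev <- replicate(2e4, generate_dot_cloud(40, 0.6, 8)$centroid - 40)
  expect_equal(sd(dev), 0.6 / sqrt(8), tolerance = 0.03)
})

test_that("schedules satisfy census, run-moment and interleaving invariants", {
  cfg <- mini_config()
  sched <- build_schedule(cfg, seed = 42)
  main <- sched[sched$kind == "main", ]

  expect_equal(nrow(main), 80)
  # one prior-only trial after every 9 main trials, alternating priors
  po <- sched[sched$kind == "prior_only", ]
  expect_equal(nrow(po), 80 %/% 9)
  expect_equal(as.vector(table(po$prior_id)), c(4, 4))
  expect_true(all(is.na(po$centroid)) && all(is.na(po$likelihood_id)))

  census <- dplyr::count(main, block, prior_id, likelihood_id)
  merged <- dplyr::left_join(cfg$pairings_by_block, census,
                             by = c("block", "prior_id", "likelihood_id"))
  expect_true(all(merged$n == merged$n_trials))

  # per-run, per-prior target moments are exact
  moments <- main |>
    dplyr::group_by(run, prior_id) |>
    dplyr::summarise(m = mean(target_x), s = population_sd(target_x),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cfg$priors, by = "prior_id")
  full_runs <- moments[moments$n >= 2, ]
  expect_lt(max(abs(full_runs$m - full_runs$mu_p)), 1e-9)
  expect_lt(max(abs(full_runs$s - full_runs$sigma_p)), 1e-9)

  # every cloud: exact SD, mean equal to stored centroid
  dots <- as.matrix(main[, paste0("dot_x_", 1:8)])
  sds <- sqrt(rowMeans((dots - rowMeans(dots))^2))
  sig <- cfg$likelihoods$sigma_l[match(main$likelihood_id,
                                       cfg$likelihoods$likelihood_id)]
  expect_lt(max(abs(sds - sig)), 1e-9)
  expect_lt(max(abs(rowMeans(dots) - main$centroid)), 1e-9)

  # reproducibility from (config, seed)
  expect_identical(sched, build_schedule(cfg, seed = 42))
})

test_that("the catch rule reproduces the overlap geometry", {
  expect_true(catch_and_score(35, 35)$caught)
  expect_true(catch_and_score(35.5, 35)$caught)   # overlap exactly 0.25
  expect_false(catch_and_score(35.6, 35)$caught)  # overlap 0.15
  expect_equal(catch_and_score(35.5, 35)$points, 1L)
  expect_equal(catch_and_score(36, 35)$points, 0L)

  # symmetric in the sign of the error, monotone in its magnitude
  d <- seq(0, 2, by = 0.05)
  left <- catch_and_score(50 - d, 50)$caught
  right <- catch_and_score(50 + d, 50)$caught
  expect_identical(left, right)
  expect_true(all(diff(as.integer(right)) <= 0))
})
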