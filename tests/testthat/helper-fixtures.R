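# Small schedule used by unit tests: two blocks of 40 main trials, the high
# likelihood entering in block 2 with counts that do not divide evenly into
# runs (exercises the shuffle chunking and the short-final-run path).
mini_config <- function(sd_mode = "population") {
  pb <- dplyr::bind_rows(
    tidyr::expand_grid(block = 1L, prior_id = c("narrow", "wide"),
                       likelihood_id = c("low", "medium")) |>
      dplyr::mutate(n_trials = 10L),
    tidyr::expand_grid(block = 2L, prior_id = c("narrow", "wide"),
                       likelihood_id = c("low", "medium", "high")) |>
      dplyr::mutate(n_trials = dplyr::case_when(likelihood_id == "high" ~ 6L,
                                                TRUE ~ 7L))
  )
  schedule_config(experiment = "mini", pairings_by_block = pb,
                  n_blocks = 2L, main_trials_per_block = 40L,
                  run_length = 20L, prior_only_period = 9L,
                  sd_mode = sd_mode)
}

# Noise-free observer parameter sets for exact-recovery tests.
noiseless_params <- function(...) {
  cohort_params(sigma_li_median = c(low = 0, medium = 0, high = 0),
                sigma_li_sdlog = 0, sigma_m_median = 0, sigma_m_sdlog = 0,
                ...)
}
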