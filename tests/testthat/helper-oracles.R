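# Independent numeric oracle for the precision-weighting formulas: the weight
# an observer places on the cue equals the sensitivity of the posterior mean
# to the cue value, computed here by trapezoid summation of the (Gaussian
# prior x Gaussian cue likelihood) posterior on a dense location grid. The
# cue SD argument is generic: sigma_l/sqrt(n) reproduces the external-noise
# model, sigma_li the internal-noise model, sqrt(sigma_l^2/n + sigma_li^2)
# the overall-variability model.
grid_posterior_weight <- function(cue_sd, sigma_p, mu_p = 50) {
  post_mean <- function(cue) {
    span <- 12 * max(sigma_p, cue_sd)
    x <- seq(min(mu_p, cue) - span, max(mu_p, cue) + span,
             length.out = 4001)
    dens <- stats::dnorm(x, mu_p, sigma_p) * stats::dnorm(cue, x, cue_sd)
    sum(x * dens) / sum(dens)
  }
  c1 <- mu_p - 1.5
  c2 <- mu_p + 2.5
  (post_mean(c2) - post_mean(c1)) / (c2 - c1)
}

# The nine (prior SD x likelihood SD) parameterizations of the task,
# including the 1.3 psw variant of the narrow prior SD.
paper_sigma_grid <- function() {
  tidyr::expand_grid(sigma_p = c(1, 1.3, 2.5), sigma_l = c(0.6, 3, 6))
}
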