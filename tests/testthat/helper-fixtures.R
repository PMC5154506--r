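# Shared fixtures and independent oracles used across the suite.

prof_a <- function(mean = 5, variance = 4, d = 5, n = 36) {
  unimodal_profile("auditory", d, mean = mean, variance = variance,
                   n_trials = n)
}

prof_v <- function(mean = 3, variance = 1, d = 3, n = 36) {
  unimodal_profile("visual", d, mean = mean, variance = variance,
                   n_trials = n)
}

# profile tibble in the compute_unimodal_profiles() layout, built directly
profiles_tbl <- function(aud_grid, aud_mean, aud_var,
                         vis_grid, vis_mean, vis_var) {
  dplyr::bind_rows(
    tibble::tibble(modality = "auditory", stimulus_distance = aud_grid,
                   mean = aud_mean, variance = aud_var, n_trials = 36L),
    tibble::tibble(modality = "visual", stimulus_distance = vis_grid,
                   mean = vis_mean, variance = vis_var, n_trials = 36L)
  )
}

posteriors_tbl <- function(vis_grid, aud_grid, p_fun) {
  g <- tidyr::expand_grid(visual_distance = vis_grid,
                          auditory_distance = aud_grid)
  dplyr::mutate(g, p_common = p_fun(g$visual_distance, g$auditory_distance),
                n_trials_used = 36L)
}

# CDF of a gaussian_estimate / mixture_estimate, used as the analytic side of
# Kolmogorov-Smirnov comparisons
estimate_cdf <- function(est, q) {
  if (inherits(est, "mixture_estimate")) {
    rowSums(vapply(seq_along(est$weights), function(i) {
      est$weights[i] * pnorm(q, est$components[[i]]$mean,
                             sqrt(est$components[[i]]$variance))
    }, numeric(length(q))))
  } else {
    pnorm(q, est$mean, sqrt(est$variance))
  }
}

# per-trial zeta-sampling enactment of probability matching: the stochastic
# process whose analytic expectation the mixture_estimate claims to be
sample_pm_responses <- function(n, p_common, common, separate) {
  zeta <- runif(n)
  take_common <- zeta < p_common
  means <- ifelse(take_common, common$mean, separate$mean)
  sds <- ifelse(take_common, sqrt(common$variance), sqrt(separate$variance))
  rnorm(n, means, sds)
}

ks_distance <- function(sample, cdf_fun) {
  x <- sort(sample)
  n <- length(x)
  cdf <- cdf_fun(x)
  max(abs(cdf - (seq_len(n) - 1) / n), abs(cdf - seq_len(n) / n))
}

# mean and variance of N(mu, sigma) censored to [lo, hi] (slider clipping),
# by numeric integration -- oracle for recovery checks on clipped responses
censored_normal_moments <- function(mu, sigma, lo = 0, hi = 10) {
  m1 <- stats::integrate(function(x) x * dnorm(x, mu, sigma), lo, hi)$value +
    lo * pnorm(lo, mu, sigma) + hi * (1 - pnorm(hi, mu, sigma))
  m2 <- stats::integrate(function(x) x^2 * dnorm(x, mu, sigma), lo, hi)$value +
    lo^2 * pnorm(lo, mu, sigma) + hi^2 * (1 - pnorm(hi, mu, sigma))
  list(mean = m1, var = m2 - m1^2)
}

# independent re-enactment of the synthetic observer's bimodal generative
# process (sensations -> similarity kernel -> zeta draw -> clipped reports),
# used as a Monte-Carlo truth oracle for matching rates
mc_matching_rate <- function(n, mu_a, s2_a, mu_v, s2_v, tau,
                             slider = c(0, 10)) {
  x_a <- rnorm(n, mu_a, sqrt(s2_a))
  x_v <- rnorm(n, mu_v, sqrt(s2_v))
  p <- exp(-(x_v - x_a)^2 / (2 * tau^2))
  match_trial <- runif(n) < p
  fused <- (x_a / s2_a + x_v / s2_v) / (1 / s2_a + 1 / s2_v)
  r_a <- pmin(slider[2], pmax(slider[1], ifelse(match_trial, fused, x_a)))
  r_v <- pmin(slider[2], pmax(slider[1], ifelse(match_trial, fused, x_v)))
  mean(r_a == r_v)
}
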