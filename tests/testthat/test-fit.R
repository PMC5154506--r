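make_table <- function(...) {
  tibble::tibble(...)
}

small_av <- function(resp_vis, resp_aud, v = 4, a = 4, subject = 1) {
  make_table(subject = subject, condition = "AV", vis_dist = v, aud_dist = a,
             resp_vis = resp_vis, resp_aud = resp_aud,
             rep = seq_along(resp_vis))
}

test_that("unimodal profiles are sample moments with a variance floor", {
  tab <- dplyr::bind_rows(
    make_table(subject = 1, condition = "A", vis_dist = NA, aud_dist = 3,
               resp_vis = NA, resp_aud = c(3, 3, 3, 3), rep = 1:4),
    make_table(subject = 1, condition = "V", vis_dist = 5, aud_dist = NA,
               resp_vis = c(2, 4), resp_aud = NA, rep = 1:2)
  )
  prof <- compute_unimodal_profiles(tab)
  aud <- prof[prof$modality == "auditory", ]
  expect_equal(aud$mean, 3)
  expect_equal(aud$variance, 1e-4)  # zero sample variance floored
  vis <- prof[prof$modality == "visual", ]
  expect_equal(vis$mean, 3)
  expect_equal(vis$variance, 2)
  expect_equal(prof$n_trials, c(4L, 2L))
})

test_that("a stimulus level without unimodal trials is named in the error", {
  tab <- dplyr::bind_rows(
    make_table(subject = 1, condition = "A", vis_dist = NA, aud_dist = 3,
               resp_vis = NA, resp_aud = c(3, 4), rep = 1:2),
    make_table(subject = 1, condition = "V", vis_dist = 5, aud_dist = NA,
               resp_vis = c(2, 4), resp_aud = NA, rep = 1:2),
    small_av(c(5, 5), c(7, 8), v = 5, a = 7)
  )
  expect_error(compute_unimodal_profiles(tab), "auditory.*7")
})

test_that("profile recovery from a synthetic observer is within sampling error", {
  cfg <- observer_config(visual_grid = 5, auditory_grid = 5,
                         repetitions = 100, n_subjects = 6, seed = 31)
  prof <- compute_unimodal_profiles(simulate_unimodal(cfg))
  n <- 600
  s2_a <- cfg$sigma2_a(5)
  expect_lt(abs(prof$mean[prof$modality == "auditory"] - 5),
            3 * sqrt(s2_a / n))
  expect_lt(abs(prof$mean[prof$modality == "visual"] - 5),
            3 * sqrt(0.25 / n))
  # unbiased sample variance close to truth (chi-square spread ~ sqrt(2/n))
  expect_equal(prof$variance[prof$modality == "auditory"], s2_a,
               tolerance = 4 * sqrt(2 / n))
})

test_that("the matching rate estimates the causal posterior", {
  tab <- small_av(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 9, 9, 9))
  expect_equal(estimate_p_common(tab, 4, 4)$p_common, 0.5)
  tab2 <- small_av(c(4, 4.4), c(4, 4.4))
  expect_equal(estimate_p_common(tab2, 4, 4)$p_common, 1)
  # (4.2, 3.9) both fall in the bin centred at 4: matching under "bin"
  tab3 <- small_av(4.2, 3.9)
  expect_equal(estimate_p_common(tab3, 4, 4)$p_common, 1)
  expect_equal(estimate_p_common(tab3, 4, 4, match_rule = "exact")$p_common, 0)
  expect_error(estimate_p_common(tab3, 1, 9), "no bimodal trials")
})

test_that("estimate_posteriors agrees with the per-pair estimator", {
  tab <- dplyr::bind_rows(small_av(c(2, 2.2), c(2.3, 5), v = 1, a = 2),
                          small_av(c(7, 7), c(7, 7), v = 7, a = 7))
  posts <- estimate_posteriors(tab)
  expect_equal(nrow(posts), 2)
  expect_equal(posts$p_common[posts$visual_distance == 1], 0.5)
  expect_equal(posts$p_common[posts$visual_distance == 7], 1)
  expect_equal(posts$n_trials_used, c(2L, 2L))
})

test_that("discretization integrates the density over unit bins", {
  # total mass always 1
  set.seed(41)
  for (i in 1:20) {
    est <- gaussian_estimate(runif(1, -2, 12), runif(1, 0.01, 9))
    expect_equal(sum(discretize(est)), 1, tolerance = 1e-9)
  }
  # near point mass lands in its own bin
  expect_gte(discretize(gaussian_estimate(5, 1e-6))[5], 0.999)
  # numeric-integration oracle for an interior Gaussian
  est <- gaussian_estimate(5, 1)
  p <- discretize(est)
  for (k in 2:9) {
    oracle <- stats::integrate(function(x) dnorm(x, 5, 1),
                               k - 0.5, k + 0.5)$value
    expect_equal(p[k], oracle, tolerance = 1e-7)
  }
  # tails absorbed into the extreme bins
  expect_equal(p[1], pnorm(1.5, 5, 1), tolerance = 1e-12)
  expect_equal(p[10], 1 - pnorm(9.5, 5, 1), tolerance = 1e-12)
  # mixtures discretize as the weighted sum of their components
  mix <- mixture_estimate(c(0.3, 0.7), list(gaussian_estimate(3, 0.8),
                                            gaussian_estimate(5, 4)))
  expect_equal(discretize(mix),
               0.3 * discretize(gaussian_estimate(3, 0.8)) +
                 0.7 * discretize(gaussian_estimate(5, 4)))
})

test_that("predicted counts follow each model's structure", {
  profs <- profiles_tbl(aud_grid = c(3, 5), aud_mean = c(3.2, 5.1),
                        aud_var = c(1.5, 1.5),
                        vis_grid = c(3, 5), vis_mean = c(3, 5),
                        vis_var = c(1.5, 0.3))
  posts <- posteriors_tbl(c(3, 5), c(3, 5), function(v, a) {
    ifelse(v == a, 0.8, 0.2)
  })
  design <- tidyr::expand_grid(visual_distance = c(3, 5),
                               auditory_distance = c(3, 5), n_trials = 6)

  # counts conserve trial mass per pair and modality
  for (m in c("NoInteraction", "MandatoryIntegration", "SensoryDominance",
              "CausalInferencePM", "CausalInferenceMA",
              "CausalInferenceMS")) {
    pc <- predict_counts(m, profs, posts, design)
    mass <- pc |>
      dplyr::group_by(visual_distance, auditory_distance, modality) |>
      dplyr::summarise(total = sum(count), .groups = "drop")
    expect_equal(mass$total, rep(6, 8), tolerance = 1e-9)
  }

  # no interaction: auditory predictions are independent of the visual cue
  pc <- predict_counts("NoInteraction", profs, posts, design)
  aud <- pc[pc$modality == "auditory", ]
  expect_equal(aud$count[aud$visual_distance == 3 & aud$auditory_distance == 5],
               aud$count[aud$visual_distance == 5 & aud$auditory_distance == 5])

  # mandatory integration with equal variances: both report modalities share
  # one vector centred midway between the cues
  profs_eq <- profiles_tbl(5, 5, 1.5, 3, 3, 1.5)
  design1 <- make_table(visual_distance = 3, auditory_distance = 5,
                        n_trials = 6)
  pc <- predict_counts("MandatoryIntegration", profs_eq, NULL, design1)
  expect_equal(pc$count[pc$modality == "auditory"],
               pc$count[pc$modality == "visual"])
  expect_equal(which.max(pc$count[pc$modality == "auditory"]), 4)

  # probability matching is the posterior-weighted sum of the common and
  # segregated count vectors, cell by cell
  pm <- predict_counts("CausalInferencePM", profs, posts, design)
  mand <- predict_counts("MandatoryIntegration", profs, posts, design)
  none <- predict_counts("NoInteraction", profs, posts, design)
  p <- posts$p_common[match(paste(pm$visual_distance, pm$auditory_distance),
                            paste(posts$visual_distance,
                                  posts$auditory_distance))]
  expect_equal(pm$count, p * mand$count + (1 - p) * none$count)

  # a pair without posterior is an explicit error for causal models
  expect_error(predict_counts("CausalInferencePM", profs, posts[-1, ], design),
               "no causal posterior")
  expect_error(predict_counts("NoInteraction",
                              profs[profs$stimulus_distance != 5 |
                                      profs$modality != "auditory", ],
                              posts, design),
               "no unimodal auditory profile")
})

test_that("OLS goodness of fit matches the normal-equations oracle", {
  idx <- make_table(visual_distance = 1, auditory_distance = 1,
                    modality = "auditory", bin = 1:6)
  pred <- dplyr::mutate(idx, count = c(1, 2, 3, 4, 5, 6))
  obs <- dplyr::mutate(idx, count = c(2, 2, 4, 4, 6, 6))
  fit <- fit_model(pred, obs, "toy", "All")
  # brute-force normal equations
  X <- cbind(1, pred$count)
  beta <- solve(t(X) %*% X, t(X) %*% obs$count)
  rss <- sum((obs$count - X %*% beta)^2)
  tss <- sum((obs$count - mean(obs$count))^2)
  expect_equal(fit$r_squared, 1 - rss / tss)
  expect_equal(fit$slope, beta[2])
  expect_equal(fit$intercept, beta[1])
  expect_equal(fit$n_points, 6L)

  # identical vectors fit perfectly (lm warns about the perfect fit)
  expect_equal(suppressWarnings(fit_model(pred, pred, "id", "All")$r_squared),
               1)

  # a constant predictor has no explanatory power
  flat <- dplyr::mutate(idx, count = 2)
  expect_warning(fit0 <- fit_model(flat, obs, "flat", "All"), "degenerate")
  expect_equal(fit0$r_squared, 0)
  expect_true(fit0$degenerate)
})

test_that("r-squared is invariant to consistent relabeling", {
  set.seed(42)
  idx <- tidyr::expand_grid(subject = 1:2, visual_distance = c(1, 3),
                            auditory_distance = 1:2, modality = "auditory",
                            bin = 1:10)
  pred <- dplyr::mutate(idx, count = runif(nrow(idx)))
  obs <- dplyr::mutate(idx, count = runif(nrow(idx)))
  base <- fit_model(pred, obs)$r_squared
  # permute rows of both tables identically (join realigns them)
  perm <- sample(nrow(pred))
  expect_equal(fit_model(pred[perm, ], obs)$r_squared, base)
  # relabel subjects consistently
  relab <- function(x) dplyr::mutate(x, subject = 3 - subject)
  expect_equal(fit_model(relab(pred), relab(obs))$r_squared, base)
})

test_that("compare_models is deterministic and collapses correctly", {
  cfg <- observer_config(visual_grid = c(3, 5), auditory_grid = c(3, 4, 5),
                         repetitions = 12, n_subjects = 2, seed = 43)
  dat <- simulate_experiment(cfg)
  fits1 <- compare_models(dat)
  fits2 <- compare_models(dat)
  expect_identical(fits1$r_squared, fits2$r_squared)  # no hidden state
  expect_setequal(unique(fits1$scope), c("All", "All (A)", "All (V)",
                                         "s1", "s2"))
  expect_equal(nrow(fits1), 6 * 5)

  # with all-segregated responses (tau -> 0 keeps matching rates ~ 0) the
  # causal models collapse onto no interaction
  cfg0 <- observer_config(visual_grid = c(3, 7), auditory_grid = c(3, 7),
                          repetitions = 20, n_subjects = 2, tau = 1e-6,
                          seed = 44, strategy = "none")
  dat0 <- simulate_experiment(cfg0)
  posts0 <- estimate_posteriors(dat0, match_rule = "exact")
  expect_true(all(posts0$p_common == 0))
  fits0 <- compare_models(dat0, match_rule = "exact")
  r <- function(m) fits0$r_squared[fits0$model == m & fits0$scope == "All"]
  expect_equal(r("CausalInferencePM"), r("NoInteraction"), tolerance = 1e-12)
  expect_equal(r("CausalInferenceMA"), r("NoInteraction"), tolerance = 1e-12)
  expect_equal(r("CausalInferenceMS"), r("NoInteraction"), tolerance = 1e-12)
})

test_that("missing conditions are explicit errors", {
  cfg <- observer_config(visual_grid = c(3, 5), auditory_grid = c(3, 5),
                         repetitions = 4, n_subjects = 1, seed = 45)
  uni <- simulate_unimodal(cfg)
  bi <- simulate_bimodal(cfg)
  expect_error(compare_models(uni), "no bimodal")
  expect_error(compare_models(bi), "no unimodal")
})

test_that("localization errors summarize as absolute deviations", {
  tab <- dplyr::bind_rows(
    make_table(subject = 1, condition = "A", vis_dist = NA, aud_dist = c(2, 4),
               resp_vis = NA, resp_aud = c(2, 4), rep = 1:2),
    make_table(subject = 1, condition = "V", vis_dist = c(2, 4), aud_dist = NA,
               resp_vis = c(3, 5), resp_aud = NA, rep = 1:2)
  )
  s <- summarize_errors(tab)
  expect_equal(s$mean_abs_error[s$condition == "A"], 0)
  expect_equal(s$mean_abs_error[s$condition == "V"], 1)
  expect_equal(s$sd_abs_error[s$condition == "V"], 0)
})

test_that("synthetic localization error matches the folded-normal oracle", {
  cfg <- observer_config(visual_grid = 5, auditory_grid = 5,
                         repetitions = 2000, n_subjects = 1, seed = 46)
  s <- summarize_errors(simulate_unimodal(cfg))
  # unbiased Gaussian noise: E|err| = sigma * sqrt(2/pi) (clipping negligible
  # at 5 m), sampling error ~ sd/sqrt(n)
  sd_v <- sqrt(0.25)
  expect_equal(s$mean_abs_error[s$condition == "V"], sd_v * sqrt(2 / pi),
               tolerance = 4 * sd_v / sqrt(2000) / (sd_v * sqrt(2 / pi)))
  sd_a <- sqrt(cfg$sigma2_a(5))
  expect_equal(s$mean_abs_error[s$condition == "A"], sd_a * sqrt(2 / pi),
               tolerance = 4 * sd_a / sqrt(2000) / (sd_a * sqrt(2 / pi)))
})
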