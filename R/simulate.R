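# Synthetic observer: generates unimodal and bimodal response tables with the
# statistical structure the analysis assumes (Gaussian sensation noise, a
# causal-inference response process), so the full pipeline is testable
# without human data. The generative common-cause mechanism (a Gaussian
# similarity kernel on the sampled sensations) is a simulator device only —
# the analysis pipeline never sees or uses it.

#' Configuration of a synthetic observer and experiment design
#'
#' Defaults emulate the experiment layout this analysis targets: visual
#' stimuli at \{1, 3, 5, 7, 9\} m, auditory stimuli at 1–10 m in 1-m steps,
#' all 50 bimodal pairs, 6 repetitions per stimulus, 6 subjects, slider
#' responses clipped to \[0, 10\] m. Sensation noise is Gaussian per modality
#' and distance; the default visual noise is constant (sd 0.5 m) and the
#' default auditory noise grows with distance (sd `0.8 + 0.18 d`), a
#' calibration aimed at the magnitudes of unimodal localization error this
#' paradigm reports (visual ~0.34 m, auditory ~1.42 m mean absolute error)
#' without claiming to reproduce them.
#'
#' Per bimodal trial the observer samples sensations `x_A`, `x_V`, perceives
#' a common cause with probability `exp(-(x_V - x_A)^2 / (2 tau^2))`
#' (similarity kernel of width `tau`), and resolves the response according to
#' `strategy`.
#'
#' @param visual_grid,auditory_grid Stimulus distances, metres.
#' @param repetitions Repetitions per stimulus (per subject).
#' @param n_subjects Number of simulated subjects.
#' @param mu_a,mu_v Mean-sensation functions of distance (default identity:
#'   an unbiased observer).
#' @param sigma2_a,sigma2_v Sensation-variance functions of distance, m^2.
#' @param tau Width of the causal similarity kernel, metres (> 0).
#' @param strategy Response resolution: `"probability_matching"` (default),
#'   `"model_averaging"`, `"model_selection"`, `"dominance"`, `"mandatory"`,
#'   or `"none"`.
#' @param seed Integer seed; fixed seed gives bit-identical tables. Each
#'   subject draws from its own substream, so a subject's rows do not depend
#'   on how many subjects are simulated.
#' @param slider Response range, metres; responses are clipped to it.
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(visual_grid = c(1, 3, 5, 7, 9),
                            auditory_grid = 1:10,
                            repetitions = 6,
                            n_subjects = 6,
                            mu_a = identity,
                            mu_v = identity,
                            sigma2_a = function(d) (0.8 + 0.18 * d)^2,
                            sigma2_v = function(d) rep(0.25, length(d)),
                            tau = 2,
                            strategy = c("probability_matching",
                                         "model_averaging", "model_selection",
                                         "dominance", "mandatory", "none"),
                            seed = 1L,
                            slider = c(0, 10)) {
  strategy <- match.arg(strategy)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  s2a <- sigma2_a(auditory_grid)
  s2v <- sigma2_v(visual_grid)
  if (any(s2a <= 0) || any(s2v <= 0)) {
    stop("sensation variances must be > 0 on the whole grid", call. = FALSE)
  }
  structure(
    list(visual_grid = as.numeric(visual_grid),
         auditory_grid = as.numeric(auditory_grid),
         repetitions = as.integer(repetitions),
         n_subjects = as.integer(n_subjects),
         mu_a = mu_a, mu_v = mu_v,
         sigma2_a = sigma2_a, sigma2_v = sigma2_v,
         tau = as.numeric(tau), strategy = strategy,
         seed = as.integer(seed), slider = as.numeric(slider)),
    class = "observer_config"
  )
}

# independent substream per (subject, block); keeps derived seeds well below
# 2^31 for small base seeds
.subject_seed <- function(seed, subject, block) {
  (abs(seed) %% 1000003L) * 1000L + subject * 10L + block
}

.clip <- function(x, slider) pmin(slider[2], pmax(slider[1], x))

#' Simulate the unimodal conditions
#'
#' Each unimodal response is a draw from the sensation distribution
#' `N(mu_i(d), sigma2_i(d))`, clipped to the slider range.
#'
#' @param config An [observer_config()].
#' @return A response table (tibble) with conditions `"A"` and `"V"`.
#' @export
simulate_unimodal <- function(config) {
  stopifnot(inherits(config, "observer_config"))
  per_subject <- function(s) {
    set.seed(.subject_seed(config$seed, s, block = 1L))
    a <- tidyr::expand_grid(aud_dist = config$auditory_grid,
                            rep = seq_len(config$repetitions))
    v <- tidyr::expand_grid(vis_dist = config$visual_grid,
                            rep = seq_len(config$repetitions))
    dplyr::bind_rows(
      tibble::tibble(subject = s, condition = "A",
                     vis_dist = NA_real_, aud_dist = a$aud_dist,
                     resp_vis = NA_real_,
                     resp_aud = .clip(stats::rnorm(nrow(a),
                                                   config$mu_a(a$aud_dist),
                                                   sqrt(config$sigma2_a(a$aud_dist))),
                                      config$slider),
                     rep = a$rep),
      tibble::tibble(subject = s, condition = "V",
                     vis_dist = v$vis_dist, aud_dist = NA_real_,
                     resp_vis = .clip(stats::rnorm(nrow(v),
                                                   config$mu_v(v$vis_dist),
                                                   sqrt(config$sigma2_v(v$vis_dist))),
                                      config$slider),
                     resp_aud = NA_real_,
                     rep = v$rep)
    )
  }
  dplyr::bind_rows(lapply(seq_len(config$n_subjects), per_subject))
}

#' Simulate the bimodal condition
#'
#' Per trial: sensations `x_A ~ N(mu_A(a), sigma2_A(a))` and
#' `x_V ~ N(mu_V(v), sigma2_V(v))` are drawn; the trial's perceived
#' common-cause probability is `exp(-(x_V - x_A)^2 / (2 tau^2))`; a uniform
#' draw `zeta` and the configured strategy turn sensations into the two
#' slider reports. Under probability matching a common-cause trial
#' (`zeta < p`) reports the inverse-variance-weighted fusion of the two
#' sensations on both sliders (hence matching answers), otherwise the raw
#' sensations are reported separately. Responses are clipped to the slider.
#'
#' @param config An [observer_config()].
#' @return A response table (tibble) with condition `"AV"`.
#' @export
simulate_bimodal <- function(config) {
  stopifnot(inherits(config, "observer_config"))
  pairs <- tidyr::expand_grid(vis_dist = config$visual_grid,
                              aud_dist = config$auditory_grid)
  per_subject <- function(s) {
    set.seed(.subject_seed(config$seed, s, block = 2L))
    tr <- tidyr::expand_grid(pairs, rep = seq_len(config$repetitions))
    s2a <- config$sigma2_a(tr$aud_dist)
    s2v <- config$sigma2_v(tr$vis_dist)
    x_a <- stats::rnorm(nrow(tr), config$mu_a(tr$aud_dist), sqrt(s2a))
    x_v <- stats::rnorm(nrow(tr), config$mu_v(tr$vis_dist), sqrt(s2v))
    p <- exp(-(x_v - x_a)^2 / (2 * config$tau^2))
    zeta <- stats::runif(nrow(tr))
    fused <- (x_a / s2a + x_v / s2v) / (1 / s2a + 1 / s2v)
    resp <- switch(config$strategy,
      probability_matching = {
        m <- zeta < p
        list(a = ifelse(m, fused, x_a), v = ifelse(m, fused, x_v))
      },
      model_averaging = list(a = p * fused + (1 - p) * x_a,
                             v = p * fused + (1 - p) * x_v),
      model_selection = {
        m <- p > 0.5
        list(a = ifelse(m, fused, x_a), v = ifelse(m, fused, x_v))
      },
      dominance = {
        vis_wins <- s2v <= s2a
        d <- ifelse(vis_wins, x_v, x_a)
        list(a = d, v = d)
      },
      mandatory = list(a = fused, v = fused),
      none = list(a = x_a, v = x_v)
    )
    tibble::tibble(subject = s, condition = "AV",
                   vis_dist = tr$vis_dist, aud_dist = tr$aud_dist,
                   resp_vis = .clip(resp$v, config$slider),
                   resp_aud = .clip(resp$a, config$slider),
                   rep = tr$rep)
  }
  dplyr::bind_rows(lapply(seq_len(config$n_subjects), per_subject))
}

#' Simulate the full experiment (unimodal + bimodal blocks)
#'
#' @param config An [observer_config()].
#' @return A response table with conditions `"A"`, `"V"` and `"AV"`.
#' @export
simulate_experiment <- function(config) {
  dplyr::bind_rows(simulate_unimodal(config), simulate_bimodal(config))
}

#' Generative ground truth of a synthetic observer
#'
#' The quantities the pipeline tries to recover, computed from the
#' configuration itself: the true sensation profiles; the per-pair expected
#' common-cause probability (the mean of the similarity kernel under the
#' sensation distributions, which is available in closed form: with
#' `delta = mu_V(v) - mu_A(a)` and `s2 = sigma2_A(a) + sigma2_V(v)`,
#' `E[p] = tau / sqrt(tau^2 + s2) * exp(-delta^2 / (2 (tau^2 + s2)))`);
#' and the causal sensory weights evaluated on those truth inputs through the
#' same [weight_surface()] code path the pipeline uses.
#'
#' @param config An [observer_config()].
#' @param target Modality for the truth weight surface.
#' @return A list with tibbles `profiles`, `posteriors`, `weights`.
#' @export
ground_truth <- function(config, target = c("auditory", "visual")) {
  stopifnot(inherits(config, "observer_config"))
  target <- match.arg(target)
  profiles <- dplyr::bind_rows(
    tibble::tibble(modality = "auditory",
                   stimulus_distance = config$auditory_grid,
                   mean = config$mu_a(config$auditory_grid),
                   variance = config$sigma2_a(config$auditory_grid),
                   n_trials = NA_integer_),
    tibble::tibble(modality = "visual",
                   stimulus_distance = config$visual_grid,
                   mean = config$mu_v(config$visual_grid),
                   variance = config$sigma2_v(config$visual_grid),
                   n_trials = NA_integer_)
  )
  pairs <- tidyr::expand_grid(visual_distance = config$visual_grid,
                              auditory_distance = config$auditory_grid)
  delta <- config$mu_v(pairs$visual_distance) -
    config$mu_a(pairs$auditory_distance)
  s2 <- config$sigma2_a(pairs$auditory_distance) +
    config$sigma2_v(pairs$visual_distance)
  k2 <- config$tau^2 + s2
  posteriors <- pairs |>
    dplyr::mutate(p_common = config$tau / sqrt(k2) * exp(-delta^2 / (2 * k2)),
                  n_trials_used = NA_integer_) |>
    dplyr::arrange(.data$auditory_distance, .data$visual_distance)
  list(profiles = profiles,
       posteriors = posteriors,
       weights = weight_surface(profiles, posteriors, target = target))
}
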