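#' Unimodal sensation profile
#'
#' The empirical Gaussian belief about the sensation elicited by a single
#' modality at a single stimulus distance: the sample mean and unbiased sample
#' variance of the unimodal reports, `N(mu, sigma^2)`. These profiles stand in
#' for the (unobservable) sensations of the bimodal condition, so every model
#' predictor consumes them.
#'
#' @param modality `"auditory"` or `"visual"`.
#' @param stimulus_distance Stimulus distance in metres.
#' @param mean Sample mean of the unimodal reports, metres, in `[0, 10]`.
#' @param variance Unbiased sample variance of the reports, m^2. Must be at
#'   least `variance_floor` (zero sample variances are floored upstream because
#'   the integration and weight formulas divide by variances).
#' @param n_trials Number of trials the profile was estimated from (>= 2).
#' @param variance_floor Smallest admissible variance, m^2.
#'
#' @return An object of class `unimodal_profile` with fields `modality`,
#'   `stimulus_distance`, `mean`, `variance`, `n_trials`.
#' @export
#' @examples
#' unimodal_profile("auditory", 5, mean = 5.2, variance = 1.8, n_trials = 36)
unimodal_profile <- function(modality, stimulus_distance, mean, variance,
                             n_trials, variance_floor = 1e-4) {
  modality <- match.arg(modality, c("auditory", "visual"))
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) ||
      variance < variance_floor) {
    stop("invalid profile: variance must be >= variance_floor (",
         variance_floor, " m^2), got ", variance, call. = FALSE)
  }
  if (!is.numeric(mean) || is.na(mean) || mean < 0 || mean > 10) {
    stop("invalid profile: mean must lie in the slider range [0, 10] m, got ",
         mean, call. = FALSE)
  }
  if (n_trials < 2) {
    stop("invalid profile: at least 2 trials are needed for a sample variance",
         call. = FALSE)
  }
  structure(
    list(modality = modality,
         stimulus_distance = as.numeric(stimulus_distance),
         mean = as.numeric(mean),
         variance = as.numeric(variance),
         n_trials = as.integer(n_trials)),
    class = "unimodal_profile"
  )
}

#' Posterior probability of a common cause for one stimulus pair
#'
#' Holds `p(C = 1 | x_V, x_A)`, the probability that the visual and auditory
#' stimuli of a pair were perceived as stemming from one physical source.
#' `p(C = 2)` is always `1 - p_common`, so only `p_common` is stored.
#'
#' @param p_common Probability of a common cause, in `[0, 1]`.
#' @param n_trials_used Number of bimodal trials the estimate is based on
#'   (`NA` for analytically constructed posteriors).
#'
#' @return An object of class `causal_posterior` with fields `p_common`,
#'   `p_separate` and `n_trials_used`.
#' @export
#' @examples
#' causal_posterior(0.3)
causal_posterior <- function(p_common, n_trials_used = NA_integer_) {
  if (!is.numeric(p_common) || length(p_common) != 1L || is.na(p_common) ||
      p_common < 0 || p_common > 1) {
    stop("p_common must be a probability in [0, 1], got ", p_common,
         call. = FALSE)
  }
  structure(
    list(p_common = as.numeric(p_common),
         p_separate = 1 - as.numeric(p_common),
         n_trials_used = as.integer(n_trials_used)),
    class = "causal_posterior"
  )
}

#' Gaussian predicted-response distribution
#'
#' A single-Gaussian prediction of the distribution of reported distance under
#' one model: `N(mean, variance)`.
#'
#' @param mean Predicted mean report, metres.
#' @param variance Predicted report variance, m^2 (> 0).
#'
#' @return An object of class `gaussian_estimate`.
#' @export
gaussian_estimate <- function(mean, variance) {
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) ||
      variance <= 0) {
    stop("invalid estimate: variance must be > 0, got ", variance,
         call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "gaussian_estimate")
}

#' Gaussian-mixture predicted-response distribution
#'
#' A weighted mixture of Gaussian estimates; the predicted response
#' distribution of the probability-matching strategy, whose two components are
#' the common-cause and separate-cause estimates sized by their causal
#' probabilities. Zero-weight components are dropped.
#'
#' @param weights Numeric vector of mixture weights; must sum to 1 within
#'   1e-12.
#' @param components List of [gaussian_estimate()] objects, same length as
#'   `weights`.
#'
#' @return An object of class `mixture_estimate` with fields `weights` and
#'   `components`.
#' @export
mixture_estimate <- function(weights, components) {
  if (length(weights) != length(components)) {
    stop("weights and components must have the same length", call. = FALSE)
  }
  if (any(weights < 0) || any(weights > 1) || abs(sum(weights) - 1) > 1e-12) {
    stop("mixture weights must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  keep <- weights > 0
  structure(list(weights = as.numeric(weights[keep]),
                 components = components[keep]),
            class = "mixture_estimate")
}

#' @export
print.unimodal_profile <- function(x, ...) {
  cat(sprintf("<unimodal_profile> %s @ %g m: mean %.3f m, variance %.4f m^2 (n = %d)\n",
              x$modality, x$stimulus_distance, x$mean, x$variance, x$n_trials))
  invisible(x)
}

#' @export
print.causal_posterior <- function(x, ...) {
  cat(sprintf("<causal_posterior> p(C=1) = %.3f, p(C=2) = %.3f (n = %s)\n",
              x$p_common, x$p_separate,
              ifelse(is.na(x$n_trials_used), "-", x$n_trials_used)))
  invisible(x)
}

#' @export
print.gaussian_estimate <- function(x, ...) {
  cat(sprintf("<gaussian_estimate> N(%.4f, %.4f)\n", x$mean, x$variance))
  invisible(x)
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("<mixture_estimate>\n")
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %.3f * N(%.4f, %.4f)\n", x$weights[i],
                x$components[[i]]$mean, x$components[[i]]$variance))
  }
  invisible(x)
}

#' Mean and variance of any predicted-response distribution
#'
#' `estimate_mean()` and `estimate_variance()` give the first two moments of a
#' [gaussian_estimate()] or [mixture_estimate()]. For mixtures the variance is
#' the full law-of-total-variance value (within-component variance plus the
#' spread of the component means).
#'
#' @param est A `gaussian_estimate` or `mixture_estimate`.
#' @return A single numeric value.
#' @export
estimate_mean <- function(est) UseMethod("estimate_mean")

#' @export
estimate_mean.gaussian_estimate <- function(est) est$mean

#' @export
estimate_mean.unimodal_profile <- function(est) est$mean

#' @export
estimate_mean.mixture_estimate <- function(est) {
  sum(est$weights * vapply(est$components, `[[`, numeric(1), "mean"))
}

#' @rdname estimate_mean
#' @export
estimate_variance <- function(est) UseMethod("estimate_variance")

#' @export
estimate_variance.gaussian_estimate <- function(est) est$variance

#' @export
estimate_variance.unimodal_profile <- function(est) est$variance

#' @export
estimate_variance.mixture_estimate <- function(est) {
  m <- vapply(est$components, `[[`, numeric(1), "mean")
  v <- vapply(est$components, `[[`, numeric(1), "variance")
  mu <- sum(est$weights * m)
  sum(est$weights * (v + (m - mu)^2))
}
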