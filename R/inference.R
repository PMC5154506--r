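# Closed-form model predictors: MLE integration, segregation, the three
# causal-resolution strategies, and the three rival models without causal
# inference. All operate on unimodal profiles / Gaussian estimates and return
# predicted response distributions; nothing here is fitted.

.check_estimate_like <- function(x, what = "profile") {
  if (is.null(x$variance) || !is.numeric(x$variance) || x$variance <= 0) {
    stop("invalid ", what, ": variance must be > 0", call. = FALSE)
  }
  invisible(x)
}

#' Common-cause (MLE) integration of two cues
#'
#' When a single underlying cause is inferred (C = 1), the auditory and visual
#' estimates coincide and equal the inverse-variance-weighted average of the
#' two sensations; the predicted variance is the product of the unimodal
#' variances over their sum, the minimum-variance combination under
#' independent Gaussian noise.
#'
#' @param profile_a,profile_v Auditory and visual [unimodal_profile()]s (or
#'   any object with `mean` and `variance` fields and positive variance).
#'
#' @return A [gaussian_estimate()]: the single shared estimate used for both
#'   modality reports under C = 1.
#' @export
#' @examples
#' a <- unimodal_profile("auditory", 5, mean = 5, variance = 4, n_trials = 36)
#' v <- unimodal_profile("visual", 3, mean = 3, variance = 1, n_trials = 36)
#' integrate_common(a, v)  # N(3.4, 0.8)
integrate_common <- function(profile_a, profile_v) {
  .check_estimate_like(profile_a)
  .check_estimate_like(profile_v)
  va <- profile_a$variance
  vv <- profile_v$variance
  w_a <- (1 / va) / (1 / va + 1 / vv)
  gaussian_estimate(mean = w_a * profile_a$mean + (1 - w_a) * profile_v$mean,
                    variance = va * vv / (va + vv))
}

#' Segregated (separate-cause) estimate
#'
#' When two causes are inferred (C = 2) the concurrent stimulus has no effect:
#' each modality's estimate is its own unimodal sensation, unchanged in both
#' mean and variance.
#'
#' @param profile A [unimodal_profile()] or `gaussian_estimate`.
#' @return A [gaussian_estimate()] with the profile's mean and variance.
#' @export
segregate <- function(profile) {
  .check_estimate_like(profile)
  gaussian_estimate(mean = profile$mean, variance = profile$variance)
}

#' Resolve an uncertain causal structure by model selection
#'
#' Returns the estimate of the more probable causal structure only: the
#' common-cause estimate when `p(C=1) > 0.5`, the separate-cause estimate when
#' `p(C=1) < 0.5`. The rule is stated with strict inequalities both ways, so
#' the tie at exactly 0.5 resolves to the separate-cause (no interaction)
#' estimate, the conservative default.
#'
#' @param post A [causal_posterior()].
#' @param common Common-cause estimate (from [integrate_common()]).
#' @param separate Separate-cause estimate (from [segregate()]).
#' @return One of `common` or `separate`, unchanged.
#' @export
resolve_model_selection <- function(post, common, separate) {
  stopifnot(inherits(post, "causal_posterior"))
  if (post$p_common > 0.5) common else separate
}

#' Resolve an uncertain causal structure by model averaging
#'
#' The final estimate is the posterior-weighted linear average of the two
#' structures' estimates; the predicted variance is, by hypothesis, the same
#' linear weighted average of the two structures' variances.
#'
#' @inheritParams resolve_model_selection
#' @return A [gaussian_estimate()]. With `p_common` 0 or 1 the result is
#'   bit-identical to `separate` / `common` respectively.
#' @export
#' @examples
#' post <- causal_posterior(0.3)
#' common <- gaussian_estimate(3.4, 0.8)
#' separate <- gaussian_estimate(5, 4)
#' resolve_model_averaging(post, common, separate)  # mean 0.3*3.4 + 0.7*5
resolve_model_averaging <- function(post, common, separate) {
  stopifnot(inherits(post, "causal_posterior"))
  p <- post$p_common
  gaussian_estimate(
    mean = p * common$mean + (1 - p) * separate$mean,
    variance = p * common$variance + (1 - p) * separate$variance
  )
}

#' Resolve an uncertain causal structure by probability matching
#'
#' Under probability matching the response follows the common-cause estimate
#' on a fraction `p(C=1)` of trials and the separate-cause estimate on the
#' rest (a uniform draw `zeta` decides each trial). The predicted response
#' distribution is therefore a two-component Gaussian mixture with weights
#' `(p_common, 1 - p_common)` — the analytic expectation of the per-trial
#' sampling process, which is what gets compared with response counts.
#' Per-trial `zeta` sampling itself lives in the synthetic observer.
#'
#' @inheritParams resolve_model_selection
#' @return A [mixture_estimate()] over `(common, separate)`.
#' @export
resolve_probability_matching <- function(post, common, separate) {
  stopifnot(inherits(post, "causal_posterior"))
  mixture_estimate(weights = c(post$p_common, post$p_separate),
                   components = list(common, separate))
}

#' Sensory-dominance prediction
#'
#' The rival model in which the most reliable cue always takes over: both
#' modality reports follow the unimodal profile with the smaller variance. At
#' exactly equal variances the visual profile is returned (vision is the more
#' accurate modality throughout this paradigm).
#'
#' @inheritParams integrate_common
#' @return A [gaussian_estimate()] equal to the lower-variance profile, used
#'   for both modality reports.
#' @export
predict_sensory_dominance <- function(profile_a, profile_v) {
  .check_estimate_like(profile_a)
  .check_estimate_like(profile_v)
  if (profile_a$variance < profile_v$variance) {
    segregate(profile_a)
  } else {
    segregate(profile_v)
  }
}

#' Mandatory-integration prediction
#'
#' The rival model in which every stimulus pair is integrated: MLE
#' inverse-variance weighting applied unconditionally, regardless of the
#' causal posterior.
#'
#' @inheritParams integrate_common
#' @return A [gaussian_estimate()], identical to [integrate_common()].
#' @export
predict_mandatory_integration <- function(profile_a, profile_v) {
  integrate_common(profile_a, profile_v)
}

#' No-interaction prediction
#'
#' The rival model in which cues never interact: each modality report is given
#' directly by its unimodal sensation, i.e. [segregate()] applied
#' unconditionally.
#'
#' @inheritParams segregate
#' @return A [gaussian_estimate()], identical to [segregate()].
#' @export
predict_no_interaction <- function(profile) {
  segregate(profile)
}
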