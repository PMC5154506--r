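# From trial-level response tables to fitted models: unimodal profile
# estimation, matching-rate causal posteriors, discretized predicted response
# counts for all six models, and OLS goodness of fit.

MODEL_NAMES <- c("SensoryDominance", "MandatoryIntegration", "NoInteraction",
                 "CausalInferencePM", "CausalInferenceMA", "CausalInferenceMS")

#' Bin a slider response onto the 1..10 m response grid
#'
#' Responses are counted in 10 unit bins centred at 1..10 m with half-open
#' edges `[c - 0.5, c + 0.5)`; the extreme bins absorb the tails, so a
#' response at exactly 0 falls into bin 1.
#'
#' @param x Numeric vector of responses in metres.
#' @return Integer vector of bin centres (1..10).
#' @export
bin_response <- function(x) {
  pmin(10L, pmax(1L, as.integer(floor(x + 0.5))))
}

.validate_response_table <- function(data) {
  needed <- c("subject", "condition", "vis_dist", "aud_dist",
              "resp_vis", "resp_aud", "rep")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("response table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$condition %in% c("A", "V", "AV"))) {
    stop("condition must be one of A, V, AV", call. = FALSE)
  }
  resp <- c(data$resp_vis, data$resp_aud)
  if (any(resp < 0 | resp > 10, na.rm = TRUE)) {
    stop("responses must lie in the slider range [0, 10] m", call. = FALSE)
  }
  invisible(data)
}

#' Estimate unimodal sensation profiles from a response table
#'
#' Computes, per modality and stimulus distance, the sample mean and unbiased
#' sample variance of the unimodal reports. These profiles are the model's
#' stand-in for the sensations of the bimodal condition. A zero sample
#' variance (all repeats identical) is floored at `variance_floor` because
#' the integration and weight formulas divide by variances.
#'
#' The required distance levels are taken from the union of unimodal and
#' bimodal stimulus distances present in the table; a level with no unimodal
#' trials (or fewer than 2) raises an error naming it.
#'
#' @param data A response table (see [read_response_table()] for the format).
#' @param subjects Optional subject id(s) to restrict the estimate to
#'   (per-subject mode); default uses all pooled data.
#' @param variance_floor Smallest admissible variance, m^2.
#' @return A tibble with columns `modality`, `stimulus_distance`, `mean`,
#'   `variance`, `n_trials`.
#' @export
compute_unimodal_profiles <- function(data, subjects = NULL,
                                      variance_floor = 1e-4) {
  .validate_response_table(data)
  if (!is.null(subjects)) data <- data[data$subject %in% subjects, ]

  req_a <- sort(unique(stats::na.omit(data$aud_dist)))
  req_v <- sort(unique(stats::na.omit(data$vis_dist)))

  uni <- dplyr::bind_rows(
    data |>
      dplyr::filter(.data$condition == "A") |>
      dplyr::transmute(modality = "auditory",
                       stimulus_distance = .data$aud_dist,
                       response = .data$resp_aud),
    data |>
      dplyr::filter(.data$condition == "V") |>
      dplyr::transmute(modality = "visual",
                       stimulus_distance = .data$vis_dist,
                       response = .data$resp_vis)
  )

  prof <- uni |>
    dplyr::group_by(.data$modality, .data$stimulus_distance) |>
    dplyr::summarise(mean = mean(.data$response),
                     variance = stats::var(.data$response),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(variance = pmax(.data$variance, variance_floor))

  for (mod in c("auditory", "visual")) {
    req <- if (mod == "auditory") req_a else req_v
    have <- prof$stimulus_distance[prof$modality == mod & prof$n_trials >= 2]
    miss <- setdiff(req, have)
    if (length(miss)) {
      stop("no usable unimodal ", mod, " trials (need >= 2) at distance(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  dplyr::arrange(prof, .data$modality, .data$stimulus_distance)
}

.profile_lookup <- function(profiles, modality, distance) {
  i <- which(profiles$modality == modality &
               profiles$stimulus_distance == distance)
  if (length(i) != 1L) {
    stop("no unimodal ", modality, " profile at distance ", distance,
         call. = FALSE)
  }
  gaussian_estimate(profiles$mean[i], profiles$variance[i])
}

#' Estimate the probability of a common cause for one stimulus pair
#'
#' The causal posterior is observed through the similarity of the two
#' reports: `p(C=1)` is the proportion of the pair's bimodal trials whose
#' visual and auditory responses match. Participants are instructed to give
#' identical answers when they perceive a single source, so the matching rate
#' is the empirical proxy for perceived common causality. The default match
#' rule counts two responses as matching when they fall in the same 1-m
#' response bin (the reports come from a continuous slider); `"exact"`
#' requires float equality.
#'
#' @param data A response table.
#' @param visual_distance,auditory_distance The stimulus pair, metres.
#' @param match_rule `"bin"` (default) or `"exact"`.
#' @param subjects Optional subject id(s) to restrict to.
#' @return A [causal_posterior()].
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   subject = 1, condition = "AV", vis_dist = 4, aud_dist = 4,
#'   resp_vis = c(4.2, 4.0, 6.0), resp_aud = c(3.9, 4.0, 2.0), rep = 1:3)
#' estimate_p_common(tab, 4, 4)  # 2 of 3 trials match in-bin
estimate_p_common <- function(data, visual_distance, auditory_distance,
                              match_rule = c("bin", "exact"),
                              subjects = NULL) {
  match_rule <- match.arg(match_rule)
  .validate_response_table(data)
  if (!is.null(subjects)) data <- data[data$subject %in% subjects, ]
  trials <- data[data$condition == "AV" &
                   data$vis_dist == visual_distance &
                   data$aud_dist == auditory_distance, ]
  if (nrow(trials) == 0L) {
    stop("no bimodal trials for pair (V = ", visual_distance, ", A = ",
         auditory_distance, ")", call. = FALSE)
  }
  matched <- if (match_rule == "bin") {
    bin_response(trials$resp_vis) == bin_response(trials$resp_aud)
  } else {
    trials$resp_vis == trials$resp_aud
  }
  causal_posterior(mean(matched), n_trials_used = nrow(trials))
}

#' Causal posteriors for every stimulus pair in a response table
#'
#' @inheritParams estimate_p_common
#' @return A tibble with columns `visual_distance`, `auditory_distance`,
#'   `p_common`, `n_trials_used`.
#' @export
estimate_posteriors <- function(data, match_rule = c("bin", "exact"),
                                subjects = NULL) {
  match_rule <- match.arg(match_rule)
  .validate_response_table(data)
  if (!is.null(subjects)) data <- data[data$subject %in% subjects, ]
  av <- data[data$condition == "AV", ]
  if (nrow(av) == 0L) stop("no bimodal (AV) trials in table", call. = FALSE)
  matched <- if (match_rule == "bin") {
    bin_response(av$resp_vis) == bin_response(av$resp_aud)
  } else {
    av$resp_vis == av$resp_aud
  }
  av |>
    dplyr::mutate(matched = matched) |>
    dplyr::group_by(visual_distance = .data$vis_dist,
                    auditory_distance = .data$aud_dist) |>
    dplyr::summarise(p_common = mean(.data$matched),
                     n_trials_used = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$auditory_distance, .data$visual_distance)
}

#' Discretize a predicted-response distribution onto the response bins
#'
#' Integrates the predicted density over each unit bin `[c - 0.5, c + 0.5)`
#' for centres 1..10; the first bin absorbs all mass below its upper edge and
#' the last all mass above its lower edge, so the vector sums to 1.
#'
#' @param est A [gaussian_estimate()] or [mixture_estimate()].
#' @param centers Bin centres (default `1:10` m).
#' @return Numeric probability vector, one entry per bin.
#' @export
discretize <- function(est, centers = 1:10) {
  edges <- c(-Inf, utils::head(centers, -1) + diff(centers) / 2, Inf)
  cdf_at <- function(q) {
    if (inherits(est, "mixture_estimate")) {
      comp <- vapply(seq_along(est$weights), function(i) {
        est$weights[i] * stats::pnorm(q, est$components[[i]]$mean,
                                      sqrt(est$components[[i]]$variance))
      }, numeric(length(q)))
      if (is.null(dim(comp))) sum(comp) else rowSums(comp)
    } else {
      stats::pnorm(q, est$mean, sqrt(est$variance))
    }
  }
  diff(cdf_at(edges))
}

.estimates_for_pair <- function(model, prof_a, prof_v, post) {
  common <- integrate_common(prof_a, prof_v)
  switch(model,
    NoInteraction = list(auditory = predict_no_interaction(prof_a),
                         visual = predict_no_interaction(prof_v)),
    MandatoryIntegration = {
      e <- predict_mandatory_integration(prof_a, prof_v)
      list(auditory = e, visual = e)
    },
    SensoryDominance = {
      e <- predict_sensory_dominance(prof_a, prof_v)
      list(auditory = e, visual = e)
    },
    CausalInferenceMS = list(
      auditory = resolve_model_selection(post, common, segregate(prof_a)),
      visual = resolve_model_selection(post, common, segregate(prof_v))),
    CausalInferenceMA = list(
      auditory = resolve_model_averaging(post, common, segregate(prof_a)),
      visual = resolve_model_averaging(post, common, segregate(prof_v))),
    CausalInferencePM = list(
      auditory = resolve_probability_matching(post, common,
                                              segregate(prof_a)),
      visual = resolve_probability_matching(post, common,
                                            segregate(prof_v))),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Predicted response counts for one model over a design
#'
#' Turns a model's predicted response distributions into expected response
#' counts: for every stimulus pair and both report modalities, the
#' discretized bin probabilities are scaled by the number of trials of that
#' pair, so predicted mass per pair equals the trial count. Causal-inference
#' models need a posterior for every pair of the design; a missing profile or
#' posterior raises an error.
#'
#' @param model One of `"SensoryDominance"`, `"MandatoryIntegration"`,
#'   `"NoInteraction"`, `"CausalInferencePM"`, `"CausalInferenceMA"`,
#'   `"CausalInferenceMS"`.
#' @param profiles Profile tibble from [compute_unimodal_profiles()].
#' @param posteriors Posterior tibble from [estimate_posteriors()] (ignored
#'   by the three non-causal models, may be `NULL` for them).
#' @param design Tibble with one row per stimulus pair: `visual_distance`,
#'   `auditory_distance`, `n_trials` (trials whose counts are predicted, e.g.
#'   per subject or pooled).
#' @param centers Response-bin centres (default `1:10`).
#' @return A tibble in long form: `visual_distance`, `auditory_distance`,
#'   `modality`, `bin`, `count`.
#' @export
predict_counts <- function(model, profiles, posteriors, design,
                           centers = 1:10) {
  model <- match.arg(model, MODEL_NAMES)
  needs_post <- model %in% c("CausalInferencePM", "CausalInferenceMA",
                             "CausalInferenceMS")
  rows <- lapply(seq_len(nrow(design)), function(i) {
    v <- design$visual_distance[i]
    a <- design$auditory_distance[i]
    n <- design$n_trials[i]
    prof_a <- .profile_lookup(profiles, "auditory", a)
    prof_v <- .profile_lookup(profiles, "visual", v)
    post <- NULL
    if (needs_post) {
      j <- which(posteriors$visual_distance == v &
                   posteriors$auditory_distance == a)
      if (length(j) != 1L) {
        stop("no causal posterior for pair (V = ", v, ", A = ", a, ")",
             call. = FALSE)
      }
      post <- causal_posterior(posteriors$p_common[j],
                               posteriors$n_trials_used[j])
    }
    est <- .estimates_for_pair(model, prof_a, prof_v, post)
    dplyr::bind_rows(lapply(c("auditory", "visual"), function(mod) {
      tibble::tibble(visual_distance = v, auditory_distance = a,
                     modality = mod, bin = as.integer(centers),
                     count = n * discretize(est[[mod]], centers))
    }))
  })
  dplyr::bind_rows(rows)
}

#' Observed response counts per subject, stimulus pair and report modality
#'
#' Bins the bimodal responses of a table onto the response grid and counts
#' them, one count vector per (subject, pair, modality).
#'
#' @param data A response table.
#' @param centers Response-bin centres (default `1:10`).
#' @return A tibble: `subject`, `visual_distance`, `auditory_distance`,
#'   `modality`, `bin`, `count`.
#' @export
observed_counts <- function(data, centers = 1:10) {
  .validate_response_table(data)
  av <- data[data$condition == "AV", ]
  if (nrow(av) == 0L) stop("no bimodal (AV) trials in table", call. = FALSE)
  long <- dplyr::bind_rows(
    av |> dplyr::transmute(.data$subject, visual_distance = .data$vis_dist,
                           auditory_distance = .data$aud_dist,
                           modality = "auditory",
                           bin = bin_response(.data$resp_aud)),
    av |> dplyr::transmute(.data$subject, visual_distance = .data$vis_dist,
                           auditory_distance = .data$aud_dist,
                           modality = "visual",
                           bin = bin_response(.data$resp_vis))
  )
  grid <- tidyr::expand_grid(
    dplyr::distinct(long, .data$subject, .data$visual_distance,
                    .data$auditory_distance, .data$modality),
    bin = as.integer(centers)
  )
  long |>
    dplyr::count(.data$subject, .data$visual_distance,
                 .data$auditory_distance, .data$modality, .data$bin,
                 name = "count") |>
    dplyr::right_join(grid, by = c("subject", "visual_distance",
                                   "auditory_distance", "modality", "bin")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::arrange(.data$subject, .data$auditory_distance,
                   .data$visual_distance, .data$modality, .data$bin)
}

#' Score one model's predicted counts against observed counts by OLS
#'
#' Simple linear regression of the observed response counts on the predicted
#' response counts over all cells in scope, as in the goodness-of-fit
#' comparison of the six models; the reported statistic is r^2. A degenerate
#' (constant) predictor has no explanatory power: r^2 is set to 0 and the
#' `degenerate` flag raised, with a warning.
#'
#' @param predicted,observed Count tibbles sharing the index columns
#'   (everything except `count`); they are joined cell by cell.
#' @param model Model name to record.
#' @param scope Scope label to record (e.g. `"All"`, `"All (A)"`, `"s3"`).
#' @return A one-row tibble: `model`, `scope`, `slope`, `intercept`,
#'   `r_squared`, `n_points`, `degenerate`.
#' @export
fit_model <- function(predicted, observed, model = "model", scope = "All") {
  by <- setdiff(intersect(names(predicted), names(observed)), "count")
  cells <- dplyr::inner_join(
    dplyr::rename(predicted, pred = "count"),
    dplyr::rename(observed, obs = "count"),
    by = by
  )
  if (nrow(cells) == 0L) stop("no common cells to fit", call. = FALSE)
  if (stats::var(cells$pred) < 1e-14) {
    warning("degenerate (constant) predictor for ", model, " [", scope,
            "]; r^2 set to 0", call. = FALSE)
    return(tibble::tibble(model = model, scope = scope, slope = NA_real_,
                          intercept = mean(cells$obs), r_squared = 0,
                          n_points = nrow(cells), degenerate = TRUE))
  }
  ols <- stats::lm(obs ~ pred, data = cells)
  tibble::tibble(model = model, scope = scope,
                 slope = stats::coef(ols)[["pred"]],
                 intercept = stats::coef(ols)[["(Intercept)"]],
                 r_squared = summary(ols)$r.squared,
                 n_points = nrow(cells), degenerate = FALSE)
}

#' Compare all six multisensory models on a response table
#'
#' The full goodness-of-fit procedure: estimate unimodal profiles and
#' matching-rate posteriors, generate each model's predicted response counts
#' for every (subject, pair, modality) cell, and regress observed on
#' predicted counts by OLS for each scope. Scopes are: `All` (both report
#' modalities pooled in one regression), `All (A)` and `All (V)` (one
#' modality each), and one per-subject scope per subject (both modalities;
#' profiles and posteriors re-estimated from that subject only). Pooled
#' scopes use profiles and posteriors estimated from all pooled data while
#' keeping per-subject count cells, so the full layout contributes
#' bins x pairs x subjects cells per modality. Counts (not rates) are
#' regressed; with a constant trial count per pair the two differ only by a
#' scale factor. No complexity correction is applied — all models have the
#' same number of parameters.
#'
#' @param data A response table with unimodal and bimodal conditions.
#' @param match_rule Match rule for [estimate_p_common()].
#' @param variance_floor Variance floor for [compute_unimodal_profiles()].
#' @param centers Response-bin centres.
#' @return A tibble of [fit_model()] rows for 6 models x all scopes, with the
#'   observed/predicted cell tables attached as attributes `observed` and
#'   `predicted` (pooled scope).
#' @export
compare_models <- function(data, match_rule = c("bin", "exact"),
                           variance_floor = 1e-4, centers = 1:10) {
  match_rule <- match.arg(match_rule)
  .validate_response_table(data)
  if (!any(data$condition == "AV")) {
    stop("response table has no bimodal (AV) condition", call. = FALSE)
  }
  if (!any(data$condition %in% c("A", "V"))) {
    stop("response table has no unimodal conditions", call. = FALSE)
  }
  obs <- observed_counts(data, centers)
  subjects <- sort(unique(obs$subject))

  subj_design <- obs |>
    dplyr::distinct(.data$subject, .data$visual_distance,
                    .data$auditory_distance) |>
    dplyr::left_join(
      data[data$condition == "AV", ] |>
        dplyr::count(.data$subject, visual_distance = .data$vis_dist,
                     auditory_distance = .data$aud_dist, name = "n_trials"),
      by = c("subject", "visual_distance", "auditory_distance")
    )

  predict_for <- function(profiles, posteriors, design_rows) {
    # one prediction per (subject, pair, modality, bin); per-subject trial
    # counts scale the shared per-pair probabilities
    dplyr::bind_rows(lapply(MODEL_NAMES, function(m) {
      dplyr::bind_rows(lapply(split(design_rows, design_rows$subject),
                              function(d) {
        predict_counts(m, profiles, posteriors,
                       d[, c("visual_distance", "auditory_distance",
                             "n_trials")], centers) |>
          dplyr::mutate(subject = d$subject[1], model = m)
      }))
    }))
  }

  prof_all <- compute_unimodal_profiles(data, variance_floor = variance_floor)
  post_all <- estimate_posteriors(data, match_rule = match_rule)
  pred_all <- predict_for(prof_all, post_all, subj_design)

  fits <- list()
  for (m in MODEL_NAMES) {
    pm <- pred_all[pred_all$model == m,
                   setdiff(names(pred_all), "model")]
    fits[[length(fits) + 1L]] <- fit_model(pm, obs, m, "All")
    for (mod in c("auditory", "visual")) {
      lab <- if (mod == "auditory") "All (A)" else "All (V)"
      fits[[length(fits) + 1L]] <-
        fit_model(pm[pm$modality == mod, ], obs[obs$modality == mod, ],
                  m, lab)
    }
  }
  for (s in subjects) {
    prof_s <- compute_unimodal_profiles(data, subjects = s,
                                        variance_floor = variance_floor)
    post_s <- estimate_posteriors(data, match_rule = match_rule, subjects = s)
    design_s <- subj_design[subj_design$subject == s, ]
    pred_s <- predict_for(prof_s, post_s, design_s)
    obs_s <- obs[obs$subject == s, ]
    for (m in MODEL_NAMES) {
      pm <- pred_s[pred_s$model == m, setdiff(names(pred_s), "model")]
      fits[[length(fits) + 1L]] <- fit_model(pm, obs_s, m, paste0("s", s))
    }
  }
  out <- dplyr::bind_rows(fits)
  attr(out, "observed") <- obs
  attr(out, "predicted") <- pred_all
  out
}

#' Pivot a model-comparison result into the wide goodness-of-fit table
#'
#' @param fits Output of [compare_models()].
#' @return A tibble with one row per model and one r^2 column per scope.
#' @export
format_fit_table <- function(fits) {
  fits |>
    dplyr::select("model", "scope", "r_squared") |>
    tidyr::pivot_wider(names_from = "scope", values_from = "r_squared") |>
    dplyr::arrange(match(.data$model, MODEL_NAMES))
}

#' Localization-error summary per condition and modality
#'
#' Mean absolute localization error `|response - stimulus distance|` and its
#' SD, per condition (unimodal auditory, unimodal visual, bimodal) and report
#' modality.
#'
#' @param data A response table.
#' @return A tibble: `condition`, `modality`, `mean_abs_error`, `sd_abs_error`,
#'   `n_trials`.
#' @export
summarize_errors <- function(data) {
  .validate_response_table(data)
  err <- dplyr::bind_rows(
    data |> dplyr::filter(.data$condition == "A") |>
      dplyr::transmute(condition = "A", modality = "auditory",
                       e = abs(.data$resp_aud - .data$aud_dist)),
    data |> dplyr::filter(.data$condition == "V") |>
      dplyr::transmute(condition = "V", modality = "visual",
                       e = abs(.data$resp_vis - .data$vis_dist)),
    data |> dplyr::filter(.data$condition == "AV") |>
      dplyr::transmute(condition = "AV", modality = "auditory",
                       e = abs(.data$resp_aud - .data$aud_dist)),
    data |> dplyr::filter(.data$condition == "AV") |>
      dplyr::transmute(condition = "AV", modality = "visual",
                       e = abs(.data$resp_vis - .data$vis_dist))
  )
  err |>
    dplyr::group_by(.data$condition, .data$modality) |>
    dplyr::summarise(mean_abs_error = mean(.data$e),
                     sd_abs_error = stats::sd(.data$e),
                     n_trials = dplyr::n(), .groups = "drop")
}
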