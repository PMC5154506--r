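# Sensory-weight calculus under causal inference and the quantification of
# interaction windows (the span of visual distances within which the visual
# cue outweighs the auditory cue on the auditory estimate).

#' MLE (inverse-variance) sensory weight
#'
#' Under full integration the weight of a cue is the normalised inverse of its
#' unimodal variance: `w_A = (1/s2_a) / (1/s2_a + 1/s2_v)`.
#'
#' @param s2_a,s2_v Auditory and visual unimodal variances, m^2 (> 0).
#' @return The auditory weight `w_A`, a fraction in (0, 1). The visual weight
#'   is its complement.
#' @export
#' @examples
#' mle_weight(4, 1)  # 0.2
mle_weight <- function(s2_a, s2_v) {
  if (any(c(s2_a, s2_v) <= 0) || any(is.na(c(s2_a, s2_v)))) {
    stop("invalid profile: variances must be > 0", call. = FALSE)
  }
  (1 / s2_a) / (1 / s2_a + 1 / s2_v)
}

#' Sensory weights accounting for causal inference
#'
#' Blends the segregated weights (self-weight 1 under separate causes) with
#' the MLE weights (under a common cause) by the causal posterior. For an
#' auditory estimate:
#' `w_A = p(C=2) + p(C=1) * s2_v / (s2_a + s2_v)` and
#' `w_V = p(C=1) * s2_a / (s2_a + s2_v)`.
#' For a visual estimate the roles of the modalities are exchanged
#' symmetrically. The two weights always sum to 1 and the self-weight is never
#' below `p(C=2)`.
#'
#' @param post A [causal_posterior()].
#' @param s2_a,s2_v Auditory and visual unimodal variances, m^2 (> 0).
#' @param target Which modality's estimate the weights refer to:
#'   `"auditory"` or `"visual"`.
#' @return An object of class `sensory_weights`: a list with fields
#'   `target_modality`, `w_a`, `w_v`.
#' @export
#' @examples
#' causal_weights(causal_posterior(0.3), s2_a = 4, s2_v = 1)  # w_A 0.76
causal_weights <- function(post, s2_a, s2_v,
                           target = c("auditory", "visual")) {
  stopifnot(inherits(post, "causal_posterior"))
  target <- match.arg(target)
  if (any(c(s2_a, s2_v) <= 0) || any(is.na(c(s2_a, s2_v)))) {
    stop("invalid profile: variances must be > 0", call. = FALSE)
  }
  p1 <- post$p_common
  p2 <- post$p_separate
  w_mle_a <- s2_v / (s2_a + s2_v)  # = mle_weight(s2_a, s2_v)
  if (target == "auditory") {
    w_a <- p2 + p1 * w_mle_a
    w_v <- p1 * (1 - w_mle_a)
  } else {
    w_v <- p2 + p1 * (1 - w_mle_a)
    w_a <- p1 * w_mle_a
  }
  structure(list(target_modality = target, w_a = w_a, w_v = w_v),
            class = "sensory_weights")
}

#' @export
print.sensory_weights <- function(x, ...) {
  cat(sprintf("<sensory_weights> %s estimate: w_A = %.3f, w_V = %.3f\n",
              x$target_modality, x$w_a, x$w_v))
  invisible(x)
}

#' Sensory-weight surface over the stimulus grid
#'
#' Evaluates [causal_weights()] for every stimulus pair of a design grid,
#' using the per-pair causal posteriors and the per-distance unimodal
#' variances. Pairs present in `posteriors` but lacking a unimodal profile, or
#' grid pairs missing from `posteriors`, yield rows with `NA` weights and a
#' warning — never a silent skip.
#'
#' @param profiles Tibble of unimodal profiles as returned by
#'   [compute_unimodal_profiles()] (columns `modality`, `stimulus_distance`,
#'   `mean`, `variance`, `n_trials`).
#' @param posteriors Tibble with one row per stimulus pair: columns
#'   `visual_distance`, `auditory_distance`, `p_common` (as returned by
#'   [estimate_posteriors()]).
#' @param target Modality of the estimate the weights refer to.
#' @return A tibble with columns `auditory_distance`, `visual_distance`,
#'   `p_common`, `w_a`, `w_v` and attribute `target`.
#' @export
weight_surface <- function(profiles, posteriors,
                           target = c("auditory", "visual")) {
  target <- match.arg(target)
  stopifnot(all(c("visual_distance", "auditory_distance", "p_common")
                %in% names(posteriors)))
  var_of <- function(mod, d) {
    v <- profiles$variance[profiles$modality == mod &
                             profiles$stimulus_distance == d]
    if (length(v) != 1L) NA_real_ else v
  }
  rows <- lapply(seq_len(nrow(posteriors)), function(i) {
    a <- posteriors$auditory_distance[i]
    v <- posteriors$visual_distance[i]
    s2a <- var_of("auditory", a)
    s2v <- var_of("visual", v)
    p <- posteriors$p_common[i]
    if (is.na(s2a) || is.na(s2v) || is.na(p)) {
      return(tibble::tibble(auditory_distance = a, visual_distance = v,
                            p_common = p, w_a = NA_real_, w_v = NA_real_))
    }
    w <- causal_weights(causal_posterior(p), s2a, s2v, target = target)
    tibble::tibble(auditory_distance = a, visual_distance = v, p_common = p,
                   w_a = w$w_a, w_v = w$w_v)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        .data$auditory_distance, .data$visual_distance)
  if (anyNA(out$w_a)) {
    bad <- out[is.na(out$w_a), c("auditory_distance", "visual_distance")]
    warning("missing profile or posterior for ", nrow(bad),
            " stimulus pair(s); their weights are NA", call. = FALSE)
  }
  attr(out, "target") <- target
  out
}

#' Interaction window along one auditory distance
#'
#' For a fixed auditory stimulus distance, the interaction window is the
#' contiguous span of visual distances over which the visual weight exceeds
#' the auditory weight on the auditory estimate (`w_v > 0.5`, strictly;
#' boundary equality is outside the window). Window edges between grid points
#' are located by linear interpolation of `w_v` at the 0.5 crossing; a run
#' that reaches the first or last grid point extends to that grid edge. If
#' several disjoint runs exceed 0.5, the widest (first on ties) is reported.
#'
#' @param surface A weight surface from [weight_surface()].
#' @param auditory_distance The auditory distance whose row to analyse.
#' @return A one-row tibble: `auditory_distance`, `window_lo`, `window_hi`,
#'   `width` (metres; `width` 0 with `NA` bounds when the window is empty).
#' @export
interaction_window <- function(surface, auditory_distance) {
  row <- surface[surface$auditory_distance == auditory_distance, ]
  if (nrow(row) == 0L) {
    stop("no surface row at auditory distance ", auditory_distance,
         call. = FALSE)
  }
  row <- row[order(row$visual_distance), ]
  x <- row$visual_distance
  w <- row$w_v
  if (anyNA(w)) {
    stop("weight surface has missing cells at auditory distance ",
         auditory_distance, call. = FALSE)
  }
  above <- w > 0.5
  empty <- tibble::tibble(auditory_distance = auditory_distance,
                          window_lo = NA_real_, window_hi = NA_real_,
                          width = 0)
  if (!any(above)) return(empty)

  cross_at <- function(i, j) {
    # linear interpolation of the 0.5 crossing between grid points i < j
    x[i] + (0.5 - w[i]) / (w[j] - w[i]) * (x[j] - x[i])
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1L) x[1L] else cross_at(i0 - 1L, i0)
    hi <- if (i1 == length(x)) x[length(x)] else cross_at(i1, i1 + 1L)
    if (is.null(best) || (hi - lo) > best$width + 1e-12) {
      best <- list(lo = lo, hi = hi, width = hi - lo)
    }
  }
  tibble::tibble(auditory_distance = auditory_distance,
                 window_lo = best$lo, window_hi = best$hi,
                 width = best$width)
}

#' Interaction windows for every auditory distance of a surface
#'
#' @param surface A weight surface from [weight_surface()].
#' @return A tibble with one [interaction_window()] row per auditory distance.
#' @export
interaction_windows <- function(surface) {
  dplyr::bind_rows(lapply(sort(unique(surface$auditory_distance)),
                          function(a) interaction_window(surface, a)))
}
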