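# Reading and writing the delimited formats that bind the pipeline together.
# All tables are plain comma-separated text with a header row; empty cells
# mean "absent" (e.g. the visual fields of a unimodal auditory trial).

RESPONSE_COLUMNS <- c("subject", "condition", "vis_dist", "aud_dist",
                      "resp_vis", "resp_aud", "rep")

#' Read a trial-level response table
#'
#' Expects the columns `subject, condition, vis_dist, aud_dist, resp_vis,
#' resp_aud, rep`; `condition` is one of `A`, `V`, `AV`. Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated response-table tibble.
#' @export
read_response_table <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_integer(),
    condition = readr::col_character(),
    vis_dist = readr::col_double(),
    aud_dist = readr::col_double(),
    resp_vis = readr::col_double(),
    resp_aud = readr::col_double(),
    rep = readr::col_integer()
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0L) {
    stop("malformed response table ", path, "; first bad row ", probs$row[1],
         ": ", probs$expected[1], " vs ", probs$actual[1], call. = FALSE)
  }
  .validate_response_table(data)
  data
}

#' Write a response table (or any tibble) as CSV at full precision
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_response_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Export a weight surface in long format
#'
#' Columns `auditory_distance, visual_distance, p_common, w_a, w_v`, full
#' float precision.
#'
#' @param surface A [weight_surface()] tibble.
#' @param path Output path.
#' @return `surface`, invisibly.
#' @export
write_weight_surface <- function(surface, path) {
  readr::write_csv(surface, path)
  invisible(surface)
}

#' Write a run manifest
#'
#' Records the configuration, package version and timestamp of a pipeline
#' run as JSON next to its outputs, so any output file can be traced back to
#' the exact settings that produced it.
#'
#' @param path Output path (JSON).
#' @param ... Named settings to record (seeds, rules, file paths, ...).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, ...) {
  manifest <- list(
    package = "avdistci",
    version = as.character(utils::packageVersion("avdistci")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    settings = list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Plot a sensory-weight surface
#'
#' One panel per auditory stimulus distance, visual and auditory weights as
#' lines over visual distance, with the 0.5 interaction threshold marked —
#' the standard way to read off where the concurrent cue dominates.
#'
#' @param surface A [weight_surface()] tibble.
#' @return A ggplot object.
#' @export
plot_weight_surface <- function(surface) {
  target <- attr(surface, "target") %||% "auditory"
  long <- surface |>
    tidyr::pivot_longer(c("w_a", "w_v"), names_to = "weight_of",
                        values_to = "weight") |>
    dplyr::mutate(weight_of = dplyr::recode(.data$weight_of,
                                            w_a = "auditory cue",
                                            w_v = "visual cue"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$visual_distance,
                                     y = .data$weight,
                                     colour = .data$weight_of)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~auditory_distance, nrow = 2,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "visual stimulus distance (m)",
                  y = paste("weight on the", target, "estimate"),
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
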