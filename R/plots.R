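#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an accuracy-versus-tolerance curve
#'
#' @param object An [accuracy_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$tolerance, y = .data$accuracy)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Tolerance level (ranks)", y = "Classification accuracy") +
    theme_minimal()
}

#' Heatmap of decision histograms
#'
#' Materials (sorted smooth/soft to rough) against assigned ranks, tile
#' intensity = probability; the visual analogue of a decision-matrix
#' histogram panel.
#'
#' @param histograms Tibble from [decision_histograms()].
#' @return A ggplot.
#' @export
plot_histograms <- function(histograms) {
  ggplot(histograms, aes(x = .data$material_id, y = .data$rank, fill = .data$prob)) +
    geom_tile() +
    scale_fill_viridis_c(name = "P(rank)") +
    labs(x = "Material (reference rank)", y = "Assigned rank") +
    theme_minimal()
}

#' Plot the training loss history of an avatar fit
#'
#' @param fit An `avatar_fit`.
#' @return A ggplot.
#' @export
plot_loss <- function(fit) {
  h <- tidy(fit)
  p <- ggplot(h, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "Epoch", y = paste(fit$spec$loss, "loss")) +
    theme_minimal()
  if (!all(is.na(h$val_loss))) {
    p <- p + geom_line(aes(y = .data$val_loss), linetype = "dashed")
  }
  p
}

#' Compare human and avatar per-material decision summaries
#'
#' Scatter of avatar expected mean rank against the participant's mean rank;
#' the identity line marks perfect mimicry.
#'
#' @param reference Tibble `material_id`, `ref_mean`.
#' @param decisions Avatar decisions tibble (`material_id`, `decision`).
#' @return A ggplot.
#' @export
plot_mimicry <- function(reference, decisions) {
  d <- decisions |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(avatar_mean = mean(.data$decision), .groups = "drop") |>
    dplyr::inner_join(reference, by = "material_id")
  ggplot(d, aes(x = .data$ref_mean, y = .data$avatar_mean)) +
    geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "Human mean rank", y = "Avatar expected rank") +
    theme_minimal()
}
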