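# ggplot2 methods for the package's result types.

#' Plot a feedback/lateral E-I matrix
#'
#' Heatmap of synapse counts per (source, target) modality pair, faceted by
#' sign; `other`-sign synapses are excluded from the display (they remain in
#' the underlying table).
#'
#' @param object A `feedback_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feedback_matrix <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$sign != "other")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$target_modality, taste_modalities()),
    y = factor(.data$source_modality, rev(taste_modalities())),
    fill = .data$synapses)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$synapses), size = 3) +
    ggplot2::facet_wrap(~sign) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "target modality", y = "source modality",
                  fill = "synapses")
}

#' Plot input-strength distributions
#'
#' Histogram of total input synapses per neuron, faceted by modality, with
#' the per-modality median marked.
#'
#' @param object An `input_strength` summary.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.input_strength <- function(object, bins = 30, ...) {
  df <- attr(object, "data")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_syn)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(data = as_tibble(object),
                        ggplot2::aes(xintercept = .data$median_total_syn),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = "total input synapses", y = "neurons")
}

#' Plot activation fractions across stimulation intensities
#'
#' @param object An `intensity_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rate_hz, y = .data$fraction,
                               colour = .data$population)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "stimulation rate (Hz)", y = "fraction activated")
}

#' Plot a synapse partition
#'
#' Stacked bars of SEZ versus non-SEZ output synapses per modality.
#'
#' @param object A `synapse_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synapse_partition <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("sez", "outside"), names_to = "location",
                        values_to = "synapses")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$synapses,
                                   fill = .data$location)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "output synapses")
}
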