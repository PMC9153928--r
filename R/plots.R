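#' Mean and 95% CI of one outcome per group and modality
#'
#' Point-and-interval display of group means (t-based CIs across
#' subjects), faceted by modality -- the layout of the trial's outcome
#' figures.
#'
#' @param scores A `dnb_scores` tibble.
#' @param outcome One of the seven block outcomes.
#' @param by `"condition"` or `"time_block"`.
#' @param segment Segment to display (default whole block).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, outcome = "wm", by = "condition",
                        segment = "whole") {
  seg <- segment
  df <- tibble::as_tibble(scores) |>
    dplyr::filter(.data$segment == seg) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "modality")))) |>
    dplyr::reframe(mean_ci_stats(.data[[outcome]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[by]], y = .data$mean)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = by, y = outcome) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Mean half-block deltas with 95% CIs
#'
#' Displays the mean second-minus-first-half change of one outcome per
#' group and modality, with the zero line the one-sample t-tests compare
#' against.
#'
#' @param deltas Output of [delta_scores()].
#' @param outcome One of `H`, `F`, `a_prime`, `wm`, `rt_mean`.
#' @param by `"condition"` or `"time_block"`.
#' @return A ggplot object.
#' @export
plot_deltas <- function(deltas, outcome = "H", by = "condition") {
  oc <- outcome
  df <- deltas |>
    dplyr::filter(.data$outcome == oc) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "modality")))) |>
    dplyr::reframe(mean_ci_stats(.data$delta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[by]], y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)
    ) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = by, y = paste("delta", oc)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_scores
#' @param object A `dnb_scores` tibble (autoplot method).
#' @param ... Passed to [plot_scores()].
#' @export
autoplot.dnb_scores <- function(object, ...) {
  plot_scores(object, ...)
}
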