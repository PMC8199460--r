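# ggplot2 views of the two result types a user inspects most: the
# calibration accuracy/WSR curve and the target vs non-target grand-average
# waveforms.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an accuracy-versus-sequences curve
#'
#' Accuracy and the written symbol rate it implies, per sequence count.
#'
#' @param object An [accuracy_by_sequences()] curve.
#' @param timing A [timing_config()] for the WSR time axis.
#' @param n Number of selectable elements.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, timing = timing_config(),
                                    n = 49, ...) {
  df <- tibble::as_tibble(object)
  df$wsr <- vapply(
    seq_len(nrow(df)),
    function(i) {
      wsr(df$accuracy[i], n, selection_duration(df$n_seq[i], timing) / 60)
    },
    numeric(1)
  )
  long <- tidyr::pivot_longer(
    dplyr::transmute(df, .data$n_seq,
      `accuracy (%)` = 100 * .data$accuracy,
      `WSR (symbols/min)` = .data$wsr
    ),
    -"n_seq",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$n_seq, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = unique(long$n_seq)) +
    ggplot2::labs(x = "sequences", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot grand-average waveforms of an epoch set
#'
#' Target versus non-target average time courses, one panel per channel;
#' the attended-stimulus positivity should peak around 250--500 ms over
#' parieto-occipital sites.
#'
#' @param object An [epoch_set()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.epoch_set <- function(object, ...) {
  ga <- grand_average(object)
  ggplot2::ggplot(
    ga,
    ggplot2::aes(.data$time_ms, .data$mean_uv, linetype = .data$condition)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, nrow = 2) +
    ggplot2::labs(
      x = "time after stimulus (ms)", y = "amplitude (uV)",
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}
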