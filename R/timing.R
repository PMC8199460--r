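#' Stimulation timing configuration
#'
#' Timing of the row-column paradigm: 250 Hz sampling, 192 ms flashes at a
#' 224 ms stimulus onset asynchrony (SOA), and a 0--800 ms post-stimulus
#' analysis window (200 samples at the default rate). An optional pause can
#' be inserted between selections; it defaults to zero and is then excluded
#' from all time-based metrics.
#'
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param stimulus_duration_s Flash duration in seconds.
#' @param soa_s Stimulus onset asynchrony in seconds; must be at least
#'   `stimulus_duration_s`.
#' @param epoch_window_s Length-2 numeric, analysis window relative to
#'   stimulus onset in seconds.
#' @param inter_selection_pause_s Pause between selections in seconds.
#' @return A `timing_config` object (a list).
#' @examples
#' t <- timing_config()
#' epoch_samples(t) # 200
#' @export
timing_config <- function(sample_rate_hz = 250,
                          stimulus_duration_s = 0.192,
                          soa_s = 0.224,
                          epoch_window_s = c(0, 0.8),
                          inter_selection_pause_s = 0) {
  stopifnot(
    is.numeric(sample_rate_hz), sample_rate_hz > 0,
    is.numeric(stimulus_duration_s), stimulus_duration_s > 0,
    is.numeric(soa_s), soa_s > 0,
    length(epoch_window_s) == 2, epoch_window_s[2] > epoch_window_s[1],
    inter_selection_pause_s >= 0
  )
  if (soa_s < stimulus_duration_s) {
    stop("`soa_s` must be at least `stimulus_duration_s`", call. = FALSE)
  }
  structure(
    list(
      sample_rate_hz = sample_rate_hz,
      stimulus_duration_s = stimulus_duration_s,
      soa_s = soa_s,
      epoch_window_s = epoch_window_s,
      inter_selection_pause_s = inter_selection_pause_s
    ),
    class = "timing_config"
  )
}

#' @rdname timing_config
#' @param timing A `timing_config`.
#' @export
epoch_samples <- function(timing) {
  as.integer(round(diff(timing$epoch_window_s) * timing$sample_rate_hz))
}

#' @rdname timing_config
#' @export
soa_samples <- function(timing) {
  as.integer(round(timing$soa_s * timing$sample_rate_hz))
}

#' Duration of one row-column selection
#'
#' One selection comprises `14 * n_seq` flashes at the configured SOA (each
#' sequence flashes all seven rows and seven columns once), plus any
#' configured inter-selection pause.
#'
#' @param n_seq Number of stimulation sequences (positive integer).
#' @param timing A [timing_config()].
#' @return Duration in seconds.
#' @examples
#' selection_duration(3) # 9.408 s
#' selection_duration(8) # 25.088 s
#' @export
selection_duration <- function(n_seq, timing = timing_config()) {
  stopifnot(is.numeric(n_seq), n_seq >= 1)
  14 * n_seq * timing$soa_s + timing$inter_selection_pause_s
}

#' @export
print.timing_config <- function(x, ...) {
  cat(
    "<timing_config> ", x$sample_rate_hz, " Hz, SOA ", x$soa_s * 1000,
    " ms, flash ", x$stimulus_duration_s * 1000, " ms, window ",
    x$epoch_window_s[1] * 1000, "-", x$epoch_window_s[2] * 1000, " ms\n",
    sep = ""
  )
  invisible(x)
}
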