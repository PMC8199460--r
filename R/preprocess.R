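# The online filter chain: 0.1 Hz first-order IIR high-pass, 9 Hz
# second-order Butterworth low-pass, and a 50 Hz notch realized as an
# order-3 Chebyshev type-I band-stop (two third-order sections in pole
# count; 0.5 dB ripple, 48-52 Hz stopband edges). Filtering is causal
# (single pass) by default to mirror the online system.

#' Design the speller's filter chain
#'
#' @param sample_rate_hz Sampling rate; must exceed 100 Hz so the 50 Hz
#'   notch lies below Nyquist.
#' @param notch_band_hz Length-2 stopband edges of the notch, Hz.
#' @param notch_ripple_db Chebyshev passband ripple, dB.
#' @param decimation Integer feature decimation factor applied after
#'   filtering when epochs are extracted for classification; 1 (off) by
#'   default.
#' @return A `filter_chain`: list of `signal::Arma`-style sections.
#' @examples
#' ch <- design_filter_chain(250)
#' round(filter_chain_attenuation_db(ch, c(5, 50)), 1)
#' @export
design_filter_chain <- function(sample_rate_hz = 250,
                                notch_band_hz = c(48, 52),
                                notch_ripple_db = 0.5,
                                decimation = 1L) {
  if (sample_rate_hz <= 100) {
    stop("`sample_rate_hz` must exceed 100 Hz", call. = FALSE)
  }
  nyq <- sample_rate_hz / 2
  stopifnot(all(notch_band_hz > 0), all(notch_band_hz < nyq), decimation >= 1)
  hp <- signal::butter(1, 0.1 / nyq, type = "high")
  lp <- signal::butter(2, 9 / nyq, type = "low")
  notch <- signal::cheby1(3, notch_ripple_db, notch_band_hz / nyq,
    type = "stop"
  )
  structure(
    list(
      sections = list(highpass = hp, lowpass = lp, notch = notch),
      sample_rate_hz = sample_rate_hz,
      decimation = as.integer(decimation)
    ),
    class = "filter_chain"
  )
}

# Complex frequency response of one b/a section at angular frequencies w.
section_response <- function(filt, w) {
  b <- filt$b
  a <- filt$a
  num <- vapply(w, function(x) sum(b * exp(-1i * x * (seq_along(b) - 1))),
    complex(1)
  )
  den <- vapply(w, function(x) sum(a * exp(-1i * x * (seq_along(a) - 1))),
    complex(1)
  )
  num / den
}

#' Magnitude response of a filter chain
#'
#' @param chain A [design_filter_chain()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @return Numeric vector of linear magnitude gains.
#' @export
filter_chain_response <- function(chain, freq_hz) {
  w <- 2 * pi * freq_hz / chain$sample_rate_hz
  h <- rep(1 + 0i, length(w))
  for (s in chain$sections) h <- h * section_response(s, w)
  abs(h)
}

#' @rdname filter_chain_response
#' @export
filter_chain_attenuation_db <- function(chain, freq_hz) {
  -20 * log10(pmax(filter_chain_response(chain, freq_hz), 1e-12))
}

#' Apply the filter chain to a multichannel signal
#'
#' Causal (forward-only) filtering by default, as run online; set
#' `zero_phase = TRUE` for offline two-pass filtering.
#'
#' @param chain A [design_filter_chain()].
#' @param x Channels x samples numeric matrix (a plain vector is treated as
#'   one channel).
#' @param zero_phase Use `signal::filtfilt` instead of a single causal pass.
#' @return Filtered signal, same shape as `x`.
#' @export
apply_filter_chain <- function(chain, x, zero_phase = FALSE) {
  stopifnot(inherits(chain, "filter_chain"))
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) {
    stop("non-finite values in input signal", call. = FALSE)
  }
  out <- x
  for (ch in seq_len(nrow(x))) {
    v <- out[ch, ]
    for (s in chain$sections) {
      v <- if (zero_phase) {
        signal::filtfilt(s, v)
      } else {
        as.numeric(signal::filter(s, v))
      }
    }
    out[ch, ] <- v
  }
  if (vec_in) out <- out[1, ]
  out
}

#' Cut stimulus-locked epochs from a continuous signal
#'
#' Extracts one `channels x samples` window per event at the configured
#' epoch window (0--800 ms, i.e. 200 samples at 250 Hz, by default),
#' preserving event order. An optional decimation factor subsamples each
#' epoch after extraction.
#'
#' @param sig Channels x samples matrix.
#' @param events Tibble with 0-based `onset_sample`, plus `stimulus_id` and
#'   `is_target` (extra columns are carried through).
#' @param timing A [timing_config()].
#' @param channel_names Channel labels; defaults to `rownames(sig)`.
#' @param decimation Keep every `decimation`-th sample of each epoch.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(sig, events, timing = timing_config(),
                           channel_names = rownames(sig),
                           decimation = 1L) {
  events <- tibble::as_tibble(events)
  win <- epoch_samples(timing)
  offset <- round(timing$epoch_window_s[1] * timing$sample_rate_hz)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(sig)))
  }
  n_ev <- nrow(events)
  keep <- seq(1L, win, by = as.integer(decimation))
  arr <- array(0, dim = c(n_ev, nrow(sig), length(keep)))
  for (i in seq_len(n_ev)) {
    start <- events$onset_sample[i] + offset # 0-based
    if (start < 0 || start + win > ncol(sig)) {
      stop("epoch window for event ", i, " (onset sample ",
        events$onset_sample[i], ") exceeds signal bounds",
        call. = FALSE
      )
    }
    arr[i, , ] <- sig[, start + keep, drop = FALSE]
  }
  epoch_set(arr, events, channel_names, timing)
}
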