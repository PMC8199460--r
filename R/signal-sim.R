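# Synthetic EEG generation. A selection is simulated as one continuous
# multichannel stream: ongoing noise plus, after every flash of the attended
# row or column, a per-channel scaled Gaussian P300 template. Epochs are cut
# from the stream afterwards, so the overlap created by the 224 ms SOA versus
# the 800 ms analysis window is reproduced exactly as the online system sees
# it.

# Band-limited 1/f-amplitude noise, unit variance per column.
one_over_f_noise <- function(n, n_cols) {
  white <- matrix(stats::rnorm(n * n_cols), n, n_cols)
  f <- c(1, seq_len(n - 1)) # avoid DC blowup
  shape <- 1 / sqrt(pmin(f, n - f + 1))
  shaped <- Re(stats::mvfft(stats::mvfft(white) * shape, inverse = TRUE)) / n
  sweep(shaped, 2, apply(shaped, 2, stats::sd), "/")
}

noise_matrix <- function(subject, n_samples, seed) {
  n_ch <- length(subject$channel_names)
  if (subject$noise_sigma_uv == 0) {
    return(matrix(0, n_ch, n_samples))
  }
  with_seed(seed, {
    m <- if (subject$noise_spectrum == "one_over_f") {
      t(one_over_f_noise(n_samples, n_ch))
    } else {
      matrix(stats::rnorm(n_ch * n_samples), n_ch, n_samples)
    }
    m * subject$noise_sigma_uv
  })
}

#' Simulate the continuous EEG of one selection
#'
#' Generates the multichannel stream for one row-column selection: flashes
#' occur every SOA, and each flash of the attended row or column adds a
#' positive Gaussian deflection (peak at the subject's P300 latency, jittered
#' per flash) scaled by the per-channel amplitude, superimposed on ongoing
#' noise. With `attended_item = NULL` the subject attends nothing (a resting
#' no-control stream: no flash is a target).
#'
#' @param subject A [make_subject_model()].
#' @param schedule A [make_flash_schedule()].
#' @param attended_item Integer `c(row, col)`, 0-based in 0--6, or `NULL`.
#' @param timing A [timing_config()].
#' @param stream_id Integer tag mixed into the noise/jitter substreams so
#'   repeated selections by the same subject differ; the output is
#'   deterministic given all arguments.
#' @return List with `signal` (channels x samples matrix, uV), `events`
#'   (tibble: `onset_sample` 0-based, `stimulus_id`, `is_target`) and
#'   `timing`.
#' @export
generate_selection_stream <- function(subject, schedule, attended_item,
                                      timing = timing_config(),
                                      stream_id = 0L) {
  stopifnot(inherits(subject, "subject_model"))
  ids <- schedule$stimulus_id
  if (length(ids) == 0) stop("empty flash schedule", call. = FALSE)
  if (!is.null(attended_item)) {
    stopifnot(length(attended_item) == 2)
    if (any(attended_item < 0) || any(attended_item > 6)) {
      stop("`attended_item` must lie in the 7x7 grid (0-based)",
        call. = FALSE
      )
    }
  }
  fs <- timing$sample_rate_hz
  soa <- soa_samples(timing)
  win <- epoch_samples(timing)
  onsets <- (seq_along(ids) - 1L) * soa
  n_samples <- onsets[length(onsets)] + win
  target_ids <- if (is.null(attended_item)) {
    integer(0)
  } else {
    c(attended_item[1], 7L + attended_item[2])
  }
  is_target <- ids %in% target_ids

  sig <- noise_matrix(
    subject, n_samples,
    substream_seed(subject$seed, "noise", schedule$seed, stream_id)
  )

  tgt_idx <- which(is_target)
  if (length(tgt_idx) > 0 && any(subject$p300_amplitude_uv > 0)) {
    jitter <- if (subject$latency_jitter_s > 0) {
      with_seed(
        substream_seed(subject$seed, "jitter", schedule$seed, stream_id),
        stats::rnorm(length(tgt_idx), 0, subject$latency_jitter_s)
      )
    } else {
      rep(0, length(tgt_idx))
    }
    t_rel <- (seq_len(win) - 1) / fs # time after flash onset, s
    amps <- subject$p300_amplitude_uv
    for (k in seq_along(tgt_idx)) {
      lat <- subject$p300_latency_s + jitter[k]
      bump <- exp(-(t_rel - lat)^2 / (2 * subject$template_width_s^2))
      cols <- onsets[tgt_idx[k]] + seq_len(win)
      sig[, cols] <- sig[, cols] + outer(amps, bump)
    }
  }
  rownames(sig) <- subject$channel_names
  list(
    signal = sig,
    events = tibble::tibble(
      onset_sample = onsets,
      stimulus_id = ids,
      is_target = is_target
    ),
    timing = timing
  )
}

#' Simulate a labeled calibration run
#'
#' Generates, selection by selection, the no-feedback calibration block in
#' which the subject attends each character of `word` in the spelling menu
#' for `n_seq` sequences (the study protocol: the 12-character string
#' "DOMOTICA2021" at 8 sequences, i.e. 1344 epochs of which 192 are
#' targets). The stream of every selection is optionally passed through a
#' filter chain before epochs are cut.
#'
#' @param subject A [make_subject_model()].
#' @param word Characters to attend, all of which must exist in `layout`.
#' @param n_seq Sequences per selection.
#' @param timing A [timing_config()].
#' @param layout A spelling [menu_layout] (defaults to the packaged one).
#' @param filter_chain Optional [design_filter_chain()] applied to each
#'   stream before epoch extraction; `NULL` leaves the signal raw.
#' @param run_id Integer tag separating independent runs of the same subject.
#' @return A labeled [epoch_set()]; events carry `selection`,
#'   `attended_row`/`attended_col` and `is_target`.
#' @export
generate_calibration_run <- function(subject, word = "DOMOTICA2021",
                                     n_seq = 8,
                                     timing = timing_config(),
                                     layout = menu_catalog()$Spelling,
                                     filter_chain = NULL,
                                     run_id = 0L) {
  chars <- strsplit(toupper(word), "")[[1]]
  if (length(chars) == 0) stop("empty calibration word", call. = FALSE)
  sets <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    pos <- locate_item(layout, chars[i])
    if (is.null(pos)) {
      stop("character not present in spelling layout: '", chars[i], "'",
        call. = FALSE
      )
    }
    sch <- make_flash_schedule(
      n_seq,
      seed = substream_seed(subject$seed, "calib-schedule", run_id, i)
    )
    stream <- generate_selection_stream(
      subject, sch, pos, timing,
      stream_id = substream_seed(run_id, "calib-stream", i)
    )
    if (!is.null(filter_chain)) {
      stream$signal <- apply_filter_chain(filter_chain, stream$signal)
    }
    es <- extract_epochs(stream$signal, stream$events, timing)
    es$events$selection <- i
    es$events$attended_row <- pos[1]
    es$events$attended_col <- pos[2]
    es$events$attended_char <- chars[i]
    sets[[i]] <- es
  }
  bind_epoch_sets(sets)
}
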