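# Plain-text interchange: epochs as long-format CSV with a JSON sidecar for
# events and timing; classifier models as JSON with features named by
# channel and millisecond offset. No proprietary EEG formats.

#' Write an epoch set to CSV (+ JSON sidecar)
#'
#' The CSV is long format (`epoch_id`, `channel`, `sample_index`,
#' `value_uv`); the sidecar stores the event table, channel names and
#' timing so the set round-trips.
#'
#' @param x An [epoch_set()].
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; defaults to `csv_path` with `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_epochs_csv <- function(x, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$epochs)
  long <- tibble::tibble(
    epoch_id = rep(seq_len(d[1]), each = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[3]), times = d[1]),
    sample_index = rep(seq_len(d[3]) - 1L, times = d[1] * d[2]),
    value_uv = as.vector(aperm(x$epochs, c(3, 2, 1)))
  )
  utils::write.csv(long, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(
      channel_names = x$channel_names,
      timing = unclass(x$timing),
      events = x$events
    ),
    json_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}

#' Read an epoch set written by [write_epochs_csv()]
#'
#' @param csv_path CSV path.
#' @param json_path Sidecar path.
#' @return An [epoch_set()].
#' @export
read_epochs_csv <- function(csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  long <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  timing <- do.call(timing_config, side$timing)
  chans <- side$channel_names
  n_ep <- max(long$epoch_id)
  n_samp <- max(long$sample_index) + 1L
  arr <- array(0, dim = c(n_ep, length(chans), n_samp))
  long$channel_i <- match(long$channel, chans)
  arr[cbind(long$epoch_id, long$channel_i, long$sample_index + 1L)] <-
    long$value_uv
  events <- tibble::as_tibble(side$events)
  epoch_set(arr, events, chans, timing)
}

#' Serialize an SWLDA model to JSON
#'
#' Features are stored as channel name plus millisecond offset, with their
#' weights, the intercept, and the training configuration.
#'
#' @param model An [fit_swlda()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swlda_json <- function(model, path) {
  stopifnot(inherits(model, "swlda_model"))
  meta <- model$training_meta
  jsonlite::write_json(
    list(
      features = model$selected_features[
        c("channel", "time_ms", "weight", "channel_index", "sample")
      ],
      intercept = model$intercept,
      config = unclass(meta$config),
      n_epochs = meta$n_epochs,
      n_channels = meta$n_channels,
      n_samples = meta$n_samples,
      sample_rate_hz = meta$sample_rate_hz
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an SWLDA model serialized by [write_swlda_json()]
#'
#' @param path JSON path.
#' @return An `swlda_model`.
#' @export
read_swlda_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- tibble::as_tibble(raw$features)
  feats$feature <- (feats$channel_index - 1L) * raw$n_samples + feats$sample
  feats <- feats[c(
    "feature", "channel", "channel_index", "sample", "time_ms", "weight"
  )]
  cfg <- do.call(swlda_config, raw$config[
    c("max_features", "p_enter", "p_remove", "label_coding", "standardize")
  ])
  structure(
    list(
      selected_features = feats,
      intercept = raw$intercept,
      training_meta = list(
        config = cfg, n_epochs = raw$n_epochs,
        n_channels = raw$n_channels, n_samples = raw$n_samples,
        sample_rate_hz = raw$sample_rate_hz
      )
    ),
    class = "swlda_model"
  )
}
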