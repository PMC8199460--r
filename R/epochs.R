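# Stimulus-locked epoch container: a [n_epochs x channels x samples] array
# plus a tibble of event metadata. Kept as an array because classifier
# features are (channel, sample) cells; the metadata beside it is tidy.

#' Construct an epoch set
#'
#' @param epochs Numeric array `[n_epochs, n_channels, n_samples]`.
#' @param events Tibble with one row per epoch; must contain at least
#'   `stimulus_id` (0--13) and `is_target` (logical). Simulated runs also
#'   carry `selection`, `onset_sample`, `attended_row`, `attended_col`.
#' @param channel_names Character vector of channel labels.
#' @param timing The [timing_config()] the epochs were cut with.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(epochs, events, channel_names, timing = timing_config()) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3)
  events <- tibble::as_tibble(events)
  if (dim(epochs)[1] != nrow(events)) {
    stop("one epoch per event required: ", dim(epochs)[1], " epochs vs ",
      nrow(events), " events",
      call. = FALSE
    )
  }
  if (dim(epochs)[2] != length(channel_names)) {
    stop("channel dimension does not match `channel_names`", call. = FALSE)
  }
  structure(
    list(
      epochs = epochs, events = events,
      channel_names = channel_names, timing = timing
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat("<epoch_set> ", d[1], " epochs x ", d[2], " channels x ", d[3],
    " samples (", sum(x$events$is_target), " targets)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @keywords internal
#' @export
n_epochs <- function(x) dim(x$epochs)[1]

# Flatten epochs to an [n x (channels*samples)] feature matrix, channel-major:
# feature (ch, s) sits at column (ch - 1) * n_samples + s.
flatten_epochs <- function(x) {
  d <- dim(x$epochs)
  matrix(aperm(x$epochs, c(1, 3, 2)), nrow = d[1], ncol = d[2] * d[3])
}

# Map flat feature indices back to (channel, sample) pairs (1-based).
feature_index_to_cs <- function(idx, n_samples) {
  data.frame(
    channel = (idx - 1L) %/% n_samples + 1L,
    sample = (idx - 1L) %% n_samples + 1L
  )
}

#' Combine epoch sets
#'
#' Binds epochs and events of compatible sets (same channels, window).
#' @param ... `epoch_set` objects.
#' @return A single `epoch_set`.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
    !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$epochs)
  for (s in sets) {
    stopifnot(inherits(s, "epoch_set"), all(dim(s$epochs)[2:3] == d[2:3]))
  }
  arr <- array(0, dim = c(sum(vapply(sets, n_epochs, 0L)), d[2], d[3]))
  at <- 0L
  for (s in sets) {
    n <- n_epochs(s)
    if (n > 0) arr[at + seq_len(n), , ] <- s$epochs
    at <- at + n
  }
  epoch_set(
    arr, dplyr::bind_rows(lapply(sets, function(s) s$events)),
    sets[[1]]$channel_names, sets[[1]]$timing
  )
}

#' Grand-average ERP of an epoch set
#'
#' Averages epochs separately for target and non-target events, returning a
#' tidy table suitable for plotting the classic attended/unattended contrast.
#'
#' @param x An `epoch_set`.
#' @return Tibble with columns `channel`, `time_ms`, `condition`, `mean_uv`.
#' @export
grand_average <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$epochs)
  t_ms <- (seq_len(d[3]) - 1) / x$timing$sample_rate_hz * 1000 +
    x$timing$epoch_window_s[1] * 1000
  avg_of <- function(mask, label) {
    if (!any(mask)) {
      return(NULL)
    }
    m <- apply(x$epochs[mask, , , drop = FALSE], c(2, 3), mean)
    tibble::tibble(
      channel = rep(x$channel_names, each = d[3]),
      time_ms = rep(t_ms, times = d[2]),
      condition = label,
      mean_uv = as.vector(t(m))
    )
  }
  dplyr::bind_rows(
    avg_of(x$events$is_target, "target"),
    avg_of(!x$events$is_target, "non-target")
  )
}
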