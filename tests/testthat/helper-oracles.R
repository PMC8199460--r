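# Shared fixtures and independent oracles.

# Naive stepwise regression oracle: refits lm() for every candidate at every
# step. Same contract as the package routine (forward: smallest p < p_enter,
# ties to lowest index; backward: drop every included p > p_remove), written
# against stats::lm only.
naive_stepwise <- function(X, y, max_features = ncol(X),
                          p_enter = 0.1, p_remove = 0.15) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  inc <- integer(0)
  repeat {
    changed <- FALSE
    if (length(inc) < max_features) {
      excl <- setdiff(seq_len(ncol(X)), inc)
      pv <- vapply(excl, function(j) {
        df <- as.data.frame(X[, c(inc, j), drop = FALSE])
        df$.y <- y
        cf <- summary(stats::lm(.y ~ ., data = df))$coefficients
        nm <- paste0("f", j)
        if (nm %in% rownames(cf)) cf[nm, 4] else NA_real_
      }, numeric(1))
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        inc <- c(inc, excl[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(inc) > 1) {
      df <- as.data.frame(X[, inc, drop = FALSE])
      df$.y <- y
      cf <- summary(stats::lm(.y ~ ., data = df))$coefficients
      pv <- vapply(inc, function(j) {
        nm <- paste0("f", j)
        if (nm %in% rownames(cf)) cf[nm, 4] else 1
      }, numeric(1))
      if (any(pv > p_remove)) {
        inc <- inc[pv <= p_remove]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(inc)
}

# Wrap an [n x p] feature matrix as an epoch_set with 2 channels so that
# flat feature j corresponds to column j (channel-major layout).
matrix_as_epochs <- function(X, is_target, n_channels = 2) {
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(p %% n_channels == 0)
  n_samp <- p / n_channels
  arr <- aperm(array(as.vector(X), c(n, n_samp, n_channels)), c(1, 3, 2))
  fs <- 250
  tm <- timing_config(
    sample_rate_hz = fs,
    epoch_window_s = c(0, n_samp / fs)
  )
  epoch_set(
    arr,
    tibble::tibble(
      onset_sample = seq_len(n) - 1L,
      stimulus_id = 0L,
      is_target = is_target
    ),
    paste0("ch", seq_len(n_channels)),
    tm
  )
}

# One cached moderate-difficulty subject + fitted classifier, shared by the
# tests that just need *a* trained linear model. Reduced calibration scale
# (8 characters, 4 sequences) keeps the suite fast.
cached_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      subject <- make_subject_model(3, 0.4)
      cfg <- study_config(
        n_subjects = 1, seeds = 3, difficulties = 0.4,
        calibration_word = "DOMOTICA", calibration_n_seq = 4
      )
      cache <<- c(list(subject = subject, config = cfg),
        run_calibration(subject, cfg)
      )
    }
    cache
  }
})
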