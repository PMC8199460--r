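# Performance metrics of the speller: bits per selection, information
# transfer rate (ITR), symbol rate and written symbol rate (WSR), output
# characters per minute (OCM), the WSR-maximizing sequence count, and the
# two questionnaire scores (SUS, Raw NASA-TLX).

#' Bits transmitted per selection
#'
#' Wolpaw's formula
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`,
#' with the continuity convention `0 * log2(0) = 0` at `P = 0` or `1`.
#'
#' @param p Selection accuracy in `[0, 1]`.
#' @param n Number of selectable elements (49 for the 7x7 menus,
#'   dummies included).
#' @return Bits per selection, in `[0, log2(n)]`.
#' @examples
#' bits_per_selection(1, 49) # log2(49) = 5.615
#' bits_per_selection(0.8614, 49)
#' @export
bits_per_selection <- function(p, n = 49) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (any(n < 2)) stop("`n` must be at least 2", call. = FALSE)
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(n) + xlog2(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (n - 1)), 0)
}

#' Information transfer rate
#'
#' `ITR = B / T` in bits per minute, where `T` is the time per selection in
#' minutes. Which time enters `T` (pure flash time or flash time plus
#' pauses) is a reporting convention; callers pass the `T` they mean.
#'
#' @inheritParams bits_per_selection
#' @param t_min Time per selection, minutes (> 0).
#' @return Bits per minute.
#' @export
itr <- function(p, n = 49, t_min) {
  if (any(t_min <= 0)) stop("`t_min` must be positive", call. = FALSE)
  bits_per_selection(p, n) / t_min
}

#' Written symbol rate
#'
#' The symbol rate is `SR = B / log2(N)`; the written symbol rate penalizes
#' the corrections an error entails:
#' `WSR = (2 SR - 1) / T` when `SR > 0.5`, and `0` otherwise (continuous at
#' the boundary).
#'
#' @inheritParams itr
#' @return Symbols per minute.
#' @export
wsr <- function(p, n = 49, t_min) {
  if (any(t_min <= 0)) stop("`t_min` must be positive", call. = FALSE)
  sr <- bits_per_selection(p, n) / log2(n)
  ifelse(sr > 0.5, (2 * sr - 1) / t_min, 0)
}

#' Output characters per minute
#'
#' Spelled characters (spaces included, predetermined command prefixes
#' excluded — see [task_character_counts()]) divided by spelling time in
#' minutes.
#'
#' @param spelled_chars Number of written characters.
#' @param spelling_minutes Time spent, minutes (> 0).
#' @return Characters per minute.
#' @export
ocm <- function(spelled_chars, spelling_minutes) {
  if (any(spelling_minutes <= 0)) {
    stop("`spelling_minutes` must be positive", call. = FALSE)
  }
  spelled_chars / spelling_minutes
}

#' Choose the online sequence count from a calibration curve
#'
#' Picks the sequence count maximizing the written symbol rate (ties to the
#' smallest count), clamped below at `min_seq`: the study protocol never
#' goes under three sequences however good the calibration looks.
#'
#' @param curve An [accuracy_by_sequences()] curve (columns `n_seq`,
#'   `accuracy`).
#' @param timing A [timing_config()]; selection time is the pure flash time
#'   unless the configuration carries a pause.
#' @param min_seq Lower clamp for the returned count.
#' @param n Number of selectable elements.
#' @return A single integer sequence count.
#' @export
choose_sequences <- function(curve, timing = timing_config(), min_seq = 3,
                             n = 49) {
  stopifnot(nrow(curve) > 0, all(c("n_seq", "accuracy") %in% names(curve)))
  w <- vapply(
    seq_len(nrow(curve)),
    function(i) {
      wsr(curve$accuracy[i], n, selection_duration(curve$n_seq[i], timing) / 60)
    },
    numeric(1)
  )
  k_star <- curve$n_seq[which.max(w)] # first max: smallest k on ties
  max(as.integer(k_star), as.integer(min_seq))
}

#' System Usability Scale score
#'
#' Standard SUS scoring of ten 1--5 Likert items: odd items contribute
#' `value - 1`, even items `5 - value`, and the sum is scaled by 2.5 to a
#' 0--100 range.
#'
#' @param items Integer vector of ten responses in 1--5.
#' @return Score in 0--100.
#' @examples
#' sus_score(rep(3, 10)) # 50
#' @export
sus_score <- function(items) {
  if (length(items) != 10 || any(items < 1 | items > 5)) {
    stop("`items` must be ten values in 1..5", call. = FALSE)
  }
  odd <- items[seq(1, 9, 2)]
  even <- items[seq(2, 10, 2)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Raw NASA-TLX total workload
#'
#' The unweighted mean of the six 0--100 subscales (mental, physical and
#' temporal demand, performance, effort, frustration).
#'
#' @param subscales Numeric vector of six values in 0--100.
#' @return Mean workload in 0--100.
#' @export
tlx_total <- function(subscales) {
  if (length(subscales) != 6 || any(subscales < 0 | subscales > 100)) {
    stop("`subscales` must be six values in 0..100", call. = FALSE)
  }
  mean(subscales)
}

#' No-control state effectiveness
#'
#' Fraction of completed no-control waits, as a percentage.
#'
#' @param successes Number of waits completed without a spurious exit.
#' @param trials Number of waits.
#' @return Percentage in 0--100.
#' @export
nc_state_effectiveness <- function(successes, trials) {
  stopifnot(trials > 0, successes >= 0, successes <= trials)
  100 * successes / trials
}

#' Selections per minute of spelling
#'
#' @param selections Number of selections made in the spelling parts.
#' @param seconds Time spent, seconds.
#' @return Selections per minute.
#' @export
spelling_selection_rate <- function(selections, seconds) {
  stopifnot(seconds > 0)
  selections / (seconds / 60)
}
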