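# Row-column stimulation engine: pseudo-random flash schedules over the
# 14 stimuli (rows 0-6, columns 7-13), score accumulation and item decision.

#' Build a pseudo-random flash schedule
#'
#' A schedule is the concatenation of `n_seq` independent uniform
#' permutations of the 14 stimuli (7 rows coded 0--6, 7 columns coded
#' 7--13), so within every consecutive block of 14 flashes each stimulus
#' appears exactly once.
#'
#' @param n_seq Number of sequences (>= 1).
#' @param seed Integer seed; the schedule is deterministic given it.
#' @param no_immediate_repeat If `TRUE`, permutations are redrawn so the same
#'   stimulus never flashes twice in a row across a sequence boundary.
#'   Off by default.
#' @return A `flash_schedule`: list with `stimulus_id` (integer vector of
#'   length `14 * n_seq`), `n_sequences` and `seed`.
#' @examples
#' s <- make_flash_schedule(3, seed = 42)
#' table(s$stimulus_id) # each stimulus exactly 3 times
#' @export
make_flash_schedule <- function(n_seq, seed, no_immediate_repeat = FALSE) {
  if (!is.numeric(n_seq) || length(n_seq) != 1 || n_seq < 1) {
    stop("`n_seq` must be a positive integer", call. = FALSE)
  }
  n_seq <- as.integer(n_seq)
  ids <- with_seed(substream_seed(seed, "schedule"), {
    out <- integer(0)
    for (k in seq_len(n_seq)) {
      perm <- sample.int(14L) - 1L
      if (no_immediate_repeat && length(out) > 0) {
        while (perm[1] == out[length(out)]) perm <- sample.int(14L) - 1L
      }
      out <- c(out, perm)
    }
    out
  })
  structure(
    list(stimulus_id = ids, n_sequences = n_seq, seed = as.integer(seed)),
    class = "flash_schedule"
  )
}

#' Decide the attended item from per-flash scores
#'
#' Classifier scores are summed per stimulus; the decided item is the
#' intersection of the highest-scoring row (stimuli 0--6) and column
#' (stimuli 7--13). Ties break toward the lowest stimulus id. Summing
#' scores is algebraically identical to scoring the per-stimulus average
#' epoch with any linear classifier.
#'
#' @param scores Numeric vector, one score per scheduled flash.
#' @param schedule The [make_flash_schedule()] the scores correspond to.
#' @return Integer vector `c(row, col)` with 0-based indices in 0--6.
#' @examples
#' sch <- make_flash_schedule(2, seed = 1)
#' sc <- as.numeric(sch$stimulus_id %in% c(2L, 12L)) # row 2, col 5 flashes
#' decide_item(sc, sch) # c(row = 2, col = 5)
#' @export
decide_item <- function(scores, schedule) {
  ids <- if (inherits(schedule, "flash_schedule")) {
    schedule$stimulus_id
  } else {
    as.integer(schedule)
  }
  if (length(scores) != length(ids)) {
    stop("`scores` must have one value per scheduled flash (",
      length(ids), "), got ", length(scores),
      call. = FALSE
    )
  }
  totals <- vapply(
    0:13,
    function(id) sum(scores[ids == id]),
    numeric(1)
  )
  row <- which.max(totals[1:7]) - 1L # which.max takes the first max: lowest id
  col <- which.max(totals[8:14]) - 1L
  c(row = row, col = col)
}
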