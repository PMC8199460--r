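# Seed plumbing: every stochastic operation draws from a named substream of a
# single integer seed, so whole runs are reproducible and independent parts of
# a simulation do not share a stream.

#' Derive a deterministic substream seed
#'
#' Hashes a base seed together with any number of labels (strings or
#' integers) into a new 32-bit seed. Used internally so that, e.g., the
#' noise of selection 7 of a subject never collides with its flash schedule.
#'
#' @param seed Integer base seed.
#' @param ... Labels (character or numeric) identifying the substream.
#' @return A single integer seed.
#' @keywords internal
substream_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (p in parts) {
    if (is.character(p)) {
      codes <- utf8ToInt(p)
      p <- sum(codes * seq_along(codes))
    }
    p <- as.double(abs(p)) %% 65521
    h <- (h * 69069 + p * 2654435761 + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
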