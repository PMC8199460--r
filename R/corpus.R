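# Word-frequency corpus backing the spelling menu's prediction column.

#' Read a word-frequency corpus
#'
#' Plain UTF-8 text, one `word<TAB>count` pair per line. Words are
#' upper-cased to match the speller's character set.
#'
#' @param path File path.
#' @return Tibble with `word` and `count`, count-descending.
#' @export
read_word_corpus <- function(path) {
  raw <- utils::read.delim(path,
    header = FALSE, col.names = c("word", "count"),
    colClasses = c("character", "numeric"), quote = "",
    fileEncoding = "UTF-8"
  )
  if (nrow(raw) == 0) stop("empty corpus file: ", path, call. = FALSE)
  tibble::as_tibble(raw) |>
    dplyr::mutate(word = toupper(.data$word)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$word)
}

#' The packaged prediction corpus
#'
#' A small fixture corpus constructed so the prediction column behaves as
#' in the reference messaging tasks: FRANCISCO is offered after one typed
#' character, EXPERIMENTO after three, UNIVERSIDAD after two, and the mail
#' receiver RICARDO after two, while higher-frequency decoys fill the seven
#' slots for shorter prefixes.
#'
#' @return Tibble with `word` and `count`.
#' @export
default_corpus <- function() {
  read_word_corpus(
    system.file("extdata", "prediction_corpus.tsv",
      package = "p300speller", mustWork = TRUE
    )
  )
}

#' Predict completions for a partial word
#'
#' Returns the up-to-seven highest-frequency corpus words having the
#' current partial word as a prefix, frequency-descending with alphabetical
#' tie-break. An empty partial word yields the globally most frequent
#' words.
#'
#' @param corpus Tibble with `word` and `count` (see [read_word_corpus()]).
#' @param partial Current partial word (characters since the last space).
#' @param n_slots Number of prediction slots (7 in the spelling menu).
#' @return Character vector of at most `n_slots` words.
#' @export
predict_words <- function(corpus, partial = "", n_slots = 7) {
  stopifnot(nrow(corpus) > 0)
  partial <- toupper(partial)
  hits <- corpus[startsWith(corpus$word, partial), , drop = FALSE]
  hits <- hits[order(-hits$count, hits$word), , drop = FALSE]
  utils::head(hits$word, n_slots)
}
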