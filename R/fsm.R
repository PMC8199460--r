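# The speller state machine: sentence buffer, menu navigation, word
# prediction and voice-command composition. All semantics are pure: every
# selection maps (state, item) -> (state, effects), which the planner, the
# simulated user and the closed-loop runner all share.

#' Voice-command templates
#'
#' Fixed sentence fragments composed by menu selections; every "send"
#' prefix ends with a trailing space so the spelled receiver follows
#' directly.
#'
#' @return Named list of command strings.
#' @export
command_templates <- function() {
  list(
    "Send WA" = "Ok Google, send a WhatsApp to ",
    "Send TG" = "Ok Google, send a Telegram to ",
    "Send SMS" = "Ok Google, send an SMS to ",
    "Send Mail" = "Ok Google, send an e-mail to ",
    "Read WA" = "Ok Google, read my WhatsApp messages",
    "Read TG" = "Ok Google, read my Telegram messages",
    "Read SMS" = "Ok Google, read my SMS messages",
    "Reply" = "Ok Google, reply ",
    "Cancel" = "Ok Google, cancel",
    "Wait" = "Ok Google, wait a while"
  )
}

#' Create a fresh speller state
#'
#' The machine starts in the no-control (NC) menu with an empty sentence
#' buffer and an empty transcript of spoken commands.
#'
#' @param corpus Prediction corpus (see [read_word_corpus()]).
#' @param catalog Menu catalog, see [menu_catalog()].
#' @param emulate_routines If `TRUE`, selecting `Reply` additionally emits
#'   the "wait a while" routine trigger used to stretch the assistant's
#'   reply window. Off by default.
#' @return A `speller_state`.
#' @export
speller_state <- function(corpus = default_corpus(),
                          catalog = menu_catalog(),
                          emulate_routines = FALSE) {
  structure(
    list(
      menu = "NC",
      sentence = "",
      spell_start = 0L, # characters of fixed command prefix in `sentence`
      pending = "none", # "ok" / "ic" while in the Confirmation menu
      transcript = character(0),
      corpus = corpus,
      catalog = catalog,
      emulate_routines = isTRUE(emulate_routines)
    ),
    class = "speller_state"
  )
}

#' @export
print.speller_state <- function(x, ...) {
  cat("<speller_state> menu ", x$menu,
    if (x$pending != "none") paste0(" (pending ", x$pending, ")"),
    ", buffer \"", x$sentence, "\", ", length(x$transcript),
    " spoken command(s)\n",
    sep = ""
  )
  invisible(x)
}

# Spelled portion of the buffer (beyond the fixed command prefix).
spelled_part <- function(state) {
  substr(state$sentence, state$spell_start + 1L, nchar(state$sentence))
}

#' Current partial word of a speller state
#'
#' The characters typed since the last space in the spelled portion of the
#' buffer; the predictor context.
#'
#' @param state A [speller_state()].
#' @return A string (possibly empty).
#' @export
current_partial <- function(state) {
  sub("^.* ", "", spelled_part(state))
}

single_chars <- c(LETTERS, as.character(0:9), ",")

#' Apply one item selection to the speller state
#'
#' Implements the full menu semantics: dummies are no-ops; `IC` in the NC
#' menu enters intentional control; send/reply commands compose their voice
#' prefix and open the spelling menu; read and cancel commands are spoken
#' immediately and return to NC; spelling items edit the buffer (characters
#' append, prediction slots replace the current partial word with the
#' predicted word plus a trailing space, `Del.`/`Del. W` delete a character
#' or word but never into the command prefix); `OK`/`IC` open the
#' confirmation menu, where `Confirm` speaks-and-clears (pending `OK`) or
#' clears-and-returns (pending `IC`) and `Back` resumes spelling with the
#' buffer intact.
#'
#' @param state A [speller_state()].
#' @param item Item label; must belong to the current menu's layout.
#' @return List with `state` (the new state) and `effects` (list:
#'   `spoken` — emitted voice command or `NULL`; `menu_before`,
#'   `menu_after`; `buffer_before`, `buffer_after`).
#' @export
apply_selection <- function(state, item) {
  stopifnot(inherits(state, "speller_state"))
  layout <- state$catalog[[state$menu]]
  if (!item %in% layout$grid) {
    stop("item '", item, "' is not in the ", state$menu, " menu",
      call. = FALSE
    )
  }
  tpl <- command_templates()
  before_menu <- state$menu
  before_buf <- state$sentence
  spoken <- NULL
  speak <- function(cmd) spoken <<- c(spoken, cmd)

  is_dummy_label <- item %in% layout$grid[layout$dummy]
  if (!is_dummy_label) {
    if (state$menu == "NC") {
      if (item == "IC") state$menu <- "IC"
    } else if (state$menu == "IC") {
      if (item %in% c("Send WA", "Send TG", "Send SMS", "Send Mail")) {
        state$sentence <- tpl[[item]]
        state$spell_start <- nchar(state$sentence)
        state$menu <- "Spelling"
      } else if (item %in% c("Read WA", "Read TG", "Read SMS")) {
        speak(tpl[[item]])
        state$sentence <- ""
        state$spell_start <- 0L
        state$menu <- "NC"
      } else if (item == "Reply") {
        if (state$emulate_routines) speak(tpl[["Wait"]])
        state$sentence <- tpl[["Reply"]]
        state$spell_start <- nchar(state$sentence)
        state$menu <- "Spelling"
      } else if (item == "Cancel") {
        speak(tpl[["Cancel"]])
        state$sentence <- ""
        state$spell_start <- 0L
        state$menu <- "NC"
      } else if (item == "NC") {
        state$menu <- "NC"
      }
    } else if (state$menu == "Spelling") {
      spelled <- spelled_part(state)
      if (item %in% single_chars) {
        state$sentence <- paste0(state$sentence, item)
      } else if (item == "SPC") {
        state$sentence <- paste0(state$sentence, " ")
      } else if (grepl("^PRED[1-7]$", item)) {
        slot <- as.integer(substr(item, 5, 5))
        preds <- predict_words(state$corpus, current_partial(state))
        if (slot <= length(preds)) {
          partial <- current_partial(state)
          head_len <- nchar(state$sentence) - nchar(partial)
          state$sentence <- paste0(
            substr(state$sentence, 1, head_len), preds[slot], " "
          )
        } # empty slot: no-op
      } else if (item == "Del.") {
        if (nchar(spelled) > 0) {
          state$sentence <- substr(state$sentence, 1, nchar(state$sentence) - 1)
        }
      } else if (item == "Del. W") {
        if (nchar(spelled) > 0) {
          state$sentence <- paste0(
            substr(state$sentence, 1, state$spell_start),
            sub("[^ ]* *$", "", spelled)
          )
        }
      } else if (item == "OK") {
        state$menu <- "Confirmation"
        state$pending <- "ok"
      } else if (item == "IC") {
        state$menu <- "Confirmation"
        state$pending <- "ic"
      }
    } else if (state$menu == "Confirmation") {
      if (item == "Confirm") {
        if (state$pending == "ok") {
          speak(state$sentence)
          state$sentence <- ""
          state$spell_start <- 0L
          state$menu <- "NC"
        } else if (state$pending == "ic") {
          state$sentence <- ""
          state$spell_start <- 0L
          state$menu <- "IC"
        }
        state$pending <- "none"
      } else if (item == "Back") {
        state$menu <- "Spelling"
        state$pending <- "none"
      }
    }
  }
  if (!is.null(spoken)) state$transcript <- c(state$transcript, spoken)
  list(
    state = state,
    effects = list(
      spoken = spoken,
      menu_before = before_menu, menu_after = state$menu,
      buffer_before = before_buf, buffer_after = state$sentence
    )
  )
}
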