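# The four messaging tasks of the study protocol, and their goal structure.
# A task is a sequence of goal utterances: "send" tasks end when the
# composed send command is confirmed and spoken; "read" tasks when the read
# command is spoken; "read_reply" tasks require the read command and then a
# confirmed reply.

#' Specify a messaging task
#'
#' `task_spec(1)`..`task_spec(4)` give the study's four tasks: (1) WhatsApp
#' to FRANCISCO with the fixed message "EXPERIMENTO EN LA UNIVERSIDAD",
#' (2) read SMS, (3) read Telegram and reply (free text, fixture default
#' "PASTA"), (4) e-mail to a receiver offered by the predictor after two
#' characters (fixture RICARDO) with a free 20--30 character message.
#'
#' @param task_id Integer 1--4, or `NULL` when all of `type`, `service` are
#'   given explicitly.
#' @param type One of `"send"`, `"read"`, `"read_reply"`.
#' @param service `"WA"`, `"TG"`, `"SMS"` or `"Mail"`.
#' @param receiver Receiver name to spell (send tasks).
#' @param message Message text (the free part for free-text tasks).
#' @param free_text Whether `message` is free text (excluded from the
#'   task's fixed minimum action count).
#' @return A `task_spec` object.
#' @export
task_spec <- function(task_id = NULL, type = NULL, service = NULL,
                      receiver = NULL, message = NULL, free_text = NULL) {
  defaults <- list(
    list(
      type = "send", service = "WA", receiver = "FRANCISCO",
      message = "EXPERIMENTO EN LA UNIVERSIDAD", free_text = FALSE
    ),
    list(
      type = "read", service = "SMS", receiver = NULL,
      message = NULL, free_text = FALSE
    ),
    list(
      type = "read_reply", service = "TG", receiver = NULL,
      message = "PASTA", free_text = TRUE
    ),
    list(
      type = "send", service = "Mail", receiver = "RICARDO",
      message = "HOLA PAULA FELIZ NAVIDAD", free_text = TRUE
    )
  )
  base <- if (!is.null(task_id)) {
    stopifnot(task_id %in% 1:4)
    defaults[[task_id]]
  } else {
    list(
      type = NULL, service = NULL, receiver = NULL, message = NULL,
      free_text = FALSE
    )
  }
  pick <- function(x, d) if (is.null(x)) d else x
  type <- match.arg(pick(type, base$type), c("send", "read", "read_reply"))
  spec <- list(
    task_id = if (is.null(task_id)) NA_integer_ else as.integer(task_id),
    type = type,
    service = pick(service, base$service),
    receiver = toupper(pick(receiver, if (is.null(base$receiver)) "" else base$receiver)),
    message = toupper(pick(message, if (is.null(base$message)) "" else base$message)),
    free_text = isTRUE(pick(free_text, base$free_text))
  )
  ok_chars <- paste0("^[", paste(c("A-Z0-9, "), collapse = ""), "]*$")
  if (!grepl(ok_chars, spec$receiver) || !grepl(ok_chars, spec$message)) {
    stop("task text uses characters outside the spelling menu", call. = FALSE)
  }
  structure(spec, class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> #", x$task_id, " ", x$type, " ", x$service,
    if (nzchar(x$receiver)) paste0(" to ", x$receiver),
    if (nzchar(x$message)) paste0(": \"", x$message, "\""),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' The four default study tasks
#' @return List of four [task_spec()] objects.
#' @export
default_tasks <- function() lapply(1:4, task_spec)

# Goal utterances of a task, in order. `include_free_text = FALSE` blanks
# the free-text message, leaving only the fixed part.
goal_utterances <- function(task, include_free_text = TRUE) {
  tpl <- command_templates()
  msg <- if (task$free_text && !include_free_text) "" else task$message
  if (task$type == "send") {
    payload <- trimws(paste(task$receiver, msg))
    paste0(tpl[[paste("Send", task$service)]], payload)
  } else if (task$type == "read") {
    tpl[[paste("Read", task$service)]]
  } else { # read_reply
    c(
      tpl[[paste("Read", task$service)]],
      trimws(paste0(tpl[["Reply"]], msg))
    )
  }
}

#' Character accounting for the output-characters-per-minute metric
#'
#' OCM counts only spelled characters (receiver, spaces and message); the
#' predetermined command prefix written by the send/reply selection is
#' excluded. For the WhatsApp task this yields 39 countable payload
#' characters and a 29-character excluded prefix.
#'
#' @param task A [task_spec()].
#' @return Tibble with `payload_chars` and `prefix_chars`.
#' @export
task_character_counts <- function(task) {
  stopifnot(inherits(task, "task_spec"))
  tpl <- command_templates()
  if (task$type == "send") {
    payload <- trimws(paste(task$receiver, task$message))
    prefix <- tpl[[paste("Send", task$service)]]
  } else if (task$type == "read_reply") {
    payload <- task$message
    prefix <- tpl[["Reply"]]
  } else {
    payload <- ""
    prefix <- tpl[[paste("Read", task$service)]]
  }
  tibble::tibble(
    payload_chars = nchar(payload),
    prefix_chars = nchar(trimws(prefix))
  )
}
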