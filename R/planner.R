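# Minimum-action planning: breadth-first search over speller states. The
# search space stays tiny because any buffer that is not a prefix of the
# current goal utterance, and any wrongly spoken command, is a dead end for
# an optimal plan.

plan_key <- function(state, phase) {
  paste(state$menu, state$pending, state$sentence, phase, sep = "\r")
}

# Candidate item labels from the current menu (dummies are no-ops and never
# part of a shortest path).
plan_actions_from <- function(state) {
  layout <- state$catalog[[state$menu]]
  unique(layout$grid[!layout$dummy])
}

# TRUE if `s` is a prefix of `full` (both plain strings).
is_prefix <- function(s, full) {
  nchar(s) <= nchar(full) && substr(full, 1, nchar(s)) == s
}

#' Plan the minimum action sequence for a task
#'
#' Breadth-first search from the no-control menu through the full menu
#' state machine (prediction slots included, resolved against the corpus at
#' every buffer state) to the task's final confirmed utterance(s). The
#' returned path length is the task's minimum number of selections.
#'
#' @param task A [task_spec()].
#' @param catalog Menu catalog ([menu_catalog()]).
#' @param corpus Prediction corpus ([default_corpus()]).
#' @param include_free_text If `FALSE`, the free-text message of a
#'   free-text task is treated as empty, giving the fixed minimum action
#'   count (e.g. 7 for the e-mail task, 6 for the Telegram reply task).
#' @param state Optional starting [speller_state()]; defaults to a fresh
#'   machine in NC. Replanning from mid-task states is supported as long
#'   as the buffer is consistent with the goal.
#' @return Character vector of item labels; its length is the minimum
#'   number of actions.
#' @examples
#' length(plan_minimum_actions(task_spec(2))) # 2: IC, Read SMS
#' @export
plan_minimum_actions <- function(task, catalog = menu_catalog(),
                                 corpus = default_corpus(),
                                 include_free_text = TRUE,
                                 state = NULL) {
  stopifnot(inherits(task, "task_spec"))
  goals <- goal_utterances(task, include_free_text)
  if (is.null(state)) state <- speller_state(corpus, catalog)
  start_phase <- planning_phase(state, goals)
  if (start_phase > length(goals)) {
    return(character(0))
  }

  # queue of (state, phase, path)
  queue <- list(list(state = state, phase = start_phase, path = character(0)))
  visited <- new.env(parent = emptyenv())
  assign(plan_key(state, start_phase), TRUE, envir = visited)
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    for (item in plan_actions_from(node$state)) {
      res <- apply_selection(node$state, item)
      phase <- node$phase
      if (!is.null(res$effects$spoken)) {
        utter <- trimws(res$effects$spoken)
        utter <- utter[utter != trimws(command_templates()[["Wait"]])]
        if (length(utter) > 0) {
          if (length(utter) > 1 || utter != trimws(goals[phase])) {
            next # wrong command spoken: dead end
          }
          phase <- phase + 1
          if (phase > length(goals)) {
            return(c(node$path, item))
          }
        }
      }
      st <- res$state
      # buffer must stay consistent with the current goal utterance
      if (nchar(st$sentence) > 0 &&
        !is_prefix(st$sentence, paste0(goals[phase], " "))) {
        next
      }
      key <- plan_key(st, phase)
      if (!exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        queue[[length(queue) + 1]] <-
          list(state = st, phase = phase, path = c(node$path, item))
      }
    }
  }
  stop("task goal unreachable from the given state", call. = FALSE)
}

# Which goal utterance is next, judged from the transcript (goals must have
# been spoken in order; each transcript entry counts once).
planning_phase <- function(state, goals) {
  spoken <- trimws(state$transcript)
  pos <- 0
  phase <- 1
  for (g in goals) {
    idx <- which(spoken == trimws(g))
    idx <- idx[idx > pos]
    if (length(idx) == 0) break
    pos <- idx[1]
    phase <- phase + 1
  }
  phase
}

#' Next item an error-aware simulated user would attend
#'
#' Follows the current minimum-action plan; after an erroneous selection it
#' repairs first (a wrong character is deleted with `Del.`, a wrong
#' predicted word with `Del. W`, an unintended confirmation menu is left
#' with `Back`, a buffer whose command prefix is wrong is abandoned via
#' `IC` + `Confirm`) and then replans from the repaired state.
#'
#' @param state Current [speller_state()].
#' @param task The active [task_spec()].
#' @param include_free_text Passed to [plan_minimum_actions()].
#' @return List with `label` (item to attend) and `position`
#'   (0-based `c(row, col)` in the current menu).
#' @export
simulated_user_policy <- function(state, task, include_free_text = TRUE) {
  goals <- goal_utterances(task, include_free_text)
  phase <- planning_phase(state, goals)
  if (phase > length(goals)) {
    return(NULL) # task complete; nothing to attend
  }
  goal_buf <- paste0(goals[phase], " ")
  label <- NULL
  if (nchar(state$sentence) > 0 && !is_prefix(state$sentence, goal_buf)) {
    prefix_bad <- !is_prefix(
      substr(state$sentence, 1, state$spell_start), goal_buf
    )
    if (state$menu == "Confirmation") {
      # a pending IC with an unusable buffer is completed (clears it);
      # anything else is backed out of so the buffer can be repaired
      label <- if (prefix_bad && state$pending == "ic") "Confirm" else "Back"
    } else if (prefix_bad) {
      label <- "IC" # wrong command prefix: abandon the buffer
    } else if (grepl(" $", state$sentence)) {
      label <- "Del. W" # wrong completed/predicted word
    } else {
      label <- "Del." # wrong character
    }
  }
  if (is.null(label)) {
    plan <- plan_minimum_actions(task,
      catalog = state$catalog, corpus = state$corpus,
      include_free_text = include_free_text, state = state
    )
    label <- plan[1]
  }
  pos <- locate_item(state$catalog[[state$menu]], label)
  if (is.null(pos)) {
    stop("policy chose '", label, "', absent from the ", state$menu, " menu",
      call. = FALSE
    )
  }
  list(label = label, position = pos)
}
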