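test_that("the planner reproduces the protocol's minimum action counts", {
  expect_length(plan_minimum_actions(task_spec(1)), 19)
  expect_identical(
    plan_minimum_actions(task_spec(2)),
    c("IC", "Read SMS")
  )
  expect_length(
    plan_minimum_actions(task_spec(3), include_free_text = FALSE), 6
  )
  expect_length(
    plan_minimum_actions(task_spec(4), include_free_text = FALSE), 7
  )
})

test_that("executing a plan completes the task exactly", {
  for (id in c(1, 2, 4)) {
    task <- task_spec(id)
    plan <- plan_minimum_actions(task)
    st <- speller_state()
    for (a in plan) st <- apply_selection(st, a)$state
    goals <- trimws(p300speller:::goal_utterances(task))
    expect_identical(trimws(st$transcript), goals)
    expect_identical(st$menu, "NC")
    expect_identical(st$sentence, "")
  }
})

test_that("plans beat exhaustive enumeration on toy payloads", {
  # independent brute force: iterative-deepening enumeration of raw action
  # strings over a restricted alphabet (every action that could possibly
  # help the toy task, plus distractors), no planner-style pruning
  exhaustive_min <- function(task, alphabet, max_depth) {
    goals <- trimws(p300speller:::goal_utterances(task))
    frontier <- list(speller_state())
    for (depth in seq_len(max_depth)) {
      nxt <- list()
      seen <- new.env(parent = emptyenv())
      for (st in frontier) {
        layout <- st$catalog[[st$menu]]
        for (a in intersect(alphabet, layout$grid)) {
          r <- apply_selection(st, a)
          spoken <- trimws(r$state$transcript)
          if (length(spoken) > 0 && !all(spoken %in% goals)) next
          if (identical(spoken, goals)) {
            return(depth)
          }
          key <- paste(r$state$menu, r$state$pending, r$state$sentence,
            paste(spoken, collapse = "|"),
            sep = "\r"
          )
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1]] <- r$state
          }
        }
      }
      frontier <- nxt
    }
    NA_integer_
  }
  toy <- task_spec(
    type = "send", service = "SMS", receiver = "AB",
    message = "", free_text = FALSE
  )
  alphabet <- c(
    "IC", "NC", "Send SMS", "Send WA", "Read WA", "A", "B", "C",
    "SPC", "Del.", "PRED1", "OK", "Confirm", "Back"
  )
  # IC, Send SMS, A, B, OK, Confirm = 6
  expect_identical(
    length(plan_minimum_actions(toy)),
    exhaustive_min(toy, alphabet, 7)
  )
  toy2 <- task_spec(type = "read", service = "WA")
  expect_identical(
    length(plan_minimum_actions(toy2)),
    exhaustive_min(toy2, alphabet, 4)
  )
})

test_that("every state reaches NC within a bounded number of selections", {
  # spot-check representative states: mid-spelling, pending confirmations
  st <- apply_selection(speller_state(), "IC")$state
  st <- apply_selection(st, "Send WA")$state
  st <- apply_selection(st, "A")$state
  # abandon spelling via IC + Confirm, then IC -> NC
  for (a in c("IC", "Confirm", "NC")) st <- apply_selection(st, a)$state
  expect_identical(st$menu, "NC")
  expect_identical(st$sentence, "")
})

test_that("the simulated user repairs errors per the replanning rules", {
  task <- task_spec(1)
  # wrong character in the buffer -> Del.
  st <- apply_selection(speller_state(), "IC")$state
  st <- apply_selection(st, "Send WA")$state
  st <- apply_selection(st, "G")$state # meant F
  expect_identical(simulated_user_policy(st, task)$label, "Del.")
  # wrong predicted word -> Del. W
  st2 <- apply_selection(speller_state(), "IC")$state
  st2 <- apply_selection(st2, "Send WA")$state
  st2 <- apply_selection(st2, "H")$state
  st2 <- apply_selection(st2, "PRED1")$state # HOLA: wrong word
  expect_match(st2$sentence, "HOLA $")
  expect_identical(simulated_user_policy(st2, task)$label, "Del. W")
  # unintended IC selection in spelling -> Back from the confirmation menu
  st3 <- apply_selection(speller_state(), "IC")$state
  st3 <- apply_selection(st3, "Send WA")$state
  st3 <- apply_selection(st3, "F")$state
  st3 <- apply_selection(st3, "IC")$state
  expect_identical(st3$menu, "Confirmation")
  expect_identical(simulated_user_policy(st3, task)$label, "Back")
  # error-free execution of the policy is exactly the 19-action plan
  st4 <- speller_state()
  actions <- character(0)
  repeat {
    intent <- simulated_user_policy(st4, task)
    if (is.null(intent)) break
    actions <- c(actions, intent$label)
    st4 <- apply_selection(st4, intent$label)$state
  }
  expect_identical(actions, plan_minimum_actions(task))
})

test_that("a wrong send command is abandoned via IC + Confirm", {
  task <- task_spec(1) # wants Send WA
  st <- apply_selection(speller_state(), "IC")$state
  st <- apply_selection(st, "Send TG")$state # wrong service
  expect_identical(simulated_user_policy(st, task)$label, "IC")
  st <- apply_selection(st, "IC")$state
  expect_identical(simulated_user_policy(st, task)$label, "Confirm")
  st <- apply_selection(st, "Confirm")$state
  expect_identical(st$menu, "IC")
  expect_identical(simulated_user_policy(st, task)$label, "Send WA")
})
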