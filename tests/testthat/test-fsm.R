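test_that("the four menus have 49 cells with the paradigm's dummy counts", {
  cat <- menu_catalog()
  expect_named(cat, c("NC", "IC", "Spelling", "Confirmation"))
  dummies <- vapply(cat, function(l) sum(l$dummy), integer(1))
  expect_identical(unname(dummies), c(48L, 39L, 0L, 47L))
  for (l in cat) expect_identical(length(l$grid), 49L)
  # IC holds exactly ten commands
  expect_identical(sum(!cat$IC$dummy), 10L)
  # spelling inventory: 26 letters, 10 digits, 7 predictions, 6 commands
  sp <- cat$Spelling$grid
  expect_true(all(c(LETTERS, 0:9, paste0("PRED", 1:7)) %in% sp))
  expect_true(all(c("SPC", ",", "Del.", "Del. W", "OK", "IC") %in% sp))
})

test_that("dummies are no-ops and NC only exits through its center", {
  st <- speller_state()
  r <- apply_selection(st, "X")
  expect_identical(r$state$menu, "NC")
  expect_identical(r$state$sentence, "")
  r <- apply_selection(st, "IC")
  expect_identical(r$state$menu, "IC")
  expect_error(apply_selection(st, "Send WA"), "not in the NC menu")
})

test_that("send commands compose their prefix and open the spelling menu", {
  st <- apply_selection(speller_state(), "IC")$state
  r <- apply_selection(st, "Send WA")
  expect_identical(r$state$menu, "Spelling")
  expect_identical(r$state$sentence, "Ok Google, send a WhatsApp to ")
  expect_null(r$effects$spoken)
  # read commands speak immediately and fall back to NC
  r2 <- apply_selection(st, "Read SMS")
  expect_identical(r2$effects$spoken, "Ok Google, read my SMS messages")
  expect_identical(r2$state$menu, "NC")
  expect_identical(r2$state$sentence, "")
  # cancel speaks and clears
  r3 <- apply_selection(st, "Cancel")
  expect_identical(r3$effects$spoken, "Ok Google, cancel")
  expect_identical(r3$state$menu, "NC")
})

test_that("spelling edits, prediction slots and deletions behave", {
  st <- apply_selection(speller_state(), "IC")$state
  st <- apply_selection(st, "Send WA")$state
  st <- apply_selection(st, "F")$state
  expect_identical(current_partial(st), "F")
  # FRANCISCO is the top prediction after one character
  expect_identical(predict_words(st$corpus, "F")[1], "FRANCISCO")
  st <- apply_selection(st, "PRED1")$state
  expect_identical(
    st$sentence,
    "Ok Google, send a WhatsApp to FRANCISCO "
  )
  # del-word removes the predicted word and its trailing space
  st2 <- apply_selection(st, "Del. W")$state
  expect_identical(st2$sentence, "Ok Google, send a WhatsApp to ")
  # del never eats into the command prefix
  st3 <- apply_selection(st2, "Del.")$state
  expect_identical(st3$sentence, "Ok Google, send a WhatsApp to ")
  # del then retyping restores the identical state
  st4 <- apply_selection(st, "E")$state
  st5 <- apply_selection(apply_selection(st4, "Del.")$state, "E")$state
  expect_identical(st4, st5)
  # an empty prediction slot is a no-op
  st6 <- apply_selection(st, "Q")$state
  st7 <- apply_selection(st6, "PRED7")$state
  expect_identical(st6$sentence, st7$sentence)
})

test_that("OK/IC are guarded by the confirmation menu", {
  st <- apply_selection(speller_state(), "IC")$state
  st <- apply_selection(st, "Send TG")$state
  st <- apply_selection(st, "H")$state
  buf <- st$sentence
  ok <- apply_selection(st, "OK")$state
  expect_identical(ok$menu, "Confirmation")
  expect_identical(ok$pending, "ok")
  # Back returns to spelling with the buffer intact
  back <- apply_selection(ok, "Back")$state
  expect_identical(back$menu, "Spelling")
  expect_identical(back$sentence, buf)
  expect_identical(back$pending, "none")
  # Confirm on OK speaks the sentence, clears, and rests in NC
  conf <- apply_selection(ok, "Confirm")
  expect_identical(conf$effects$spoken, buf)
  expect_identical(conf$state$menu, "NC")
  expect_identical(conf$state$sentence, "")
  # Confirm on a pending IC clears silently and returns to IC
  ic <- apply_selection(st, "IC")$state
  expect_identical(ic$pending, "ic")
  conf2 <- apply_selection(ic, "Confirm")
  expect_null(conf2$effects$spoken)
  expect_identical(conf2$state$menu, "IC")
  expect_identical(conf2$state$sentence, "")
})

test_that("predictions come frequency-descending with alphabetical ties and
           prefix filtering", {
  corpus <- tibble::tibble(
    word = c("ABBA", "ABLE", "ABOUT", "AC"),
    count = c(5, 7, 7, 1)
  )
  expect_identical(
    predict_words(corpus, "AB"),
    c("ABLE", "ABOUT", "ABBA")
  )
  expect_identical(predict_words(corpus, "Z"), character(0))
  expect_length(predict_words(default_corpus(), ""), 7)
})

test_that("the packaged corpus reproduces the protocol's prediction offsets", {
  corpus <- default_corpus()
  slots <- function(partial) predict_words(corpus, partial)
  # receiver after one character; long words after three and two
  expect_true("FRANCISCO" %in% slots("F"))
  expect_false("FRANCISCO" %in% slots(""))
  expect_false("EXPERIMENTO" %in% slots("E"))
  expect_false("EXPERIMENTO" %in% slots("EX"))
  expect_true("EXPERIMENTO" %in% slots("EXP"))
  expect_false("UNIVERSIDAD" %in% slots("U"))
  expect_true("UNIVERSIDAD" %in% slots("UN"))
  expect_false("RICARDO" %in% slots("R"))
  expect_true("RICARDO" %in% slots("RI"))
  # no shortcut completions for the short words of the fixed message
  expect_false(any(c("EN", "LA") %in% c(slots("E"), slots("L"))))
})
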