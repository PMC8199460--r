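# Closed-loop study runner: calibration -> classifier -> sequence choice ->
# the four messaging tasks with a simulated error-aware user, plus the
# packaged reference results of the original online study.

#' Study configuration
#'
#' Bundles everything a simulated study needs. Defaults reproduce the
#' reference protocol: 12 subjects, calibration on the 12-character string
#' "DOMOTICA2021" at 8 sequences, WSR-based sequence choice with a floor of
#' 3, the four messaging tasks, and a 70% accuracy exclusion threshold.
#'
#' @param n_subjects Number of simulated participants.
#' @param seeds Integer vector of per-subject seeds (default `1:n_subjects`).
#' @param difficulties Per-subject difficulty in `[0, 1]` (recycled).
#' @param timing A [timing_config()].
#' @param swlda An [swlda_config()].
#' @param tasks List of [task_spec()]s; defaults to [default_tasks()].
#' @param corpus Prediction corpus.
#' @param calibration_word Characters attended during calibration.
#' @param calibration_n_seq Sequences per calibration selection.
#' @param accuracy_threshold_pct Exclusion threshold on online accuracy.
#' @param min_seq Sequence-count floor for [choose_sequences()].
#' @param step_cap Selection cap per task before it is marked failed.
#' @param nc_waits Simulate the two one-minute no-control waits.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 12,
                         seeds = seq_len(n_subjects),
                         difficulties = 0.5,
                         timing = timing_config(),
                         swlda = swlda_config(),
                         tasks = default_tasks(),
                         corpus = default_corpus(),
                         calibration_word = "DOMOTICA2021",
                         calibration_n_seq = 8,
                         accuracy_threshold_pct = 70,
                         min_seq = 3,
                         step_cap = 200,
                         nc_waits = TRUE) {
  stopifnot(
    accuracy_threshold_pct > 0, accuracy_threshold_pct < 100,
    length(seeds) == n_subjects
  )
  structure(
    list(
      n_subjects = n_subjects, seeds = as.integer(seeds),
      difficulties = rep_len(difficulties, n_subjects),
      timing = timing, swlda = swlda, tasks = tasks, corpus = corpus,
      calibration_word = calibration_word,
      calibration_n_seq = as.integer(calibration_n_seq),
      accuracy_threshold_pct = accuracy_threshold_pct,
      min_seq = as.integer(min_seq), step_cap = as.integer(step_cap),
      nc_waits = isTRUE(nc_waits)
    ),
    class = "study_config"
  )
}

#' Calibrate one simulated subject
#'
#' Simulates the no-feedback calibration block, filters it with the online
#' chain, fits the SWLDA classifier, evaluates the accuracy-versus-
#' sequences curve on a fresh simulated run of the same word, and applies
#' the WSR criterion (floor `min_seq`) to pick the online sequence count.
#'
#' @param subject A [make_subject_model()].
#' @param config A [study_config()].
#' @return List with `model`, `curve` (an accuracy curve), `n_seq`, and the
#'   filter `chain`.
#' @export
run_calibration <- function(subject, config = study_config()) {
  chain <- design_filter_chain(config$timing$sample_rate_hz)
  layout <- menu_catalog()$Spelling
  calib <- generate_calibration_run(
    subject, config$calibration_word, config$calibration_n_seq,
    config$timing, layout, chain,
    run_id = 1L
  )
  model <- fit_swlda(calib, config$swlda)
  test <- generate_calibration_run(
    subject, config$calibration_word, config$calibration_n_seq,
    config$timing, layout, chain,
    run_id = 2L
  )
  curve <- accuracy_by_sequences(model, test)
  list(
    model = model,
    curve = curve,
    n_seq = choose_sequences(curve, config$timing, config$min_seq),
    chain = chain
  )
}

# One closed-loop selection: simulate, filter, epoch, score, decide.
# Returns the decided 0-based (row, col).
run_selection <- function(subject, model, chain, n_seq, attended, timing,
                          seed_tag) {
  sch <- make_flash_schedule(
    n_seq,
    seed = substream_seed(subject$seed, "online-schedule", seed_tag)
  )
  stream <- generate_selection_stream(
    subject, sch, attended, timing,
    stream_id = substream_seed(1L, "online-stream", seed_tag)
  )
  sig <- apply_filter_chain(chain, stream$signal)
  eps <- extract_epochs(sig, stream$events, timing,
    channel_names = subject$channel_names
  )
  decide_item(score_epochs(model, eps), sch)
}

#' Run one messaging task in closed loop
#'
#' The simulated user attends the item the error-aware policy dictates;
#' the EEG of each selection is generated, filtered, epoch-extracted,
#' scored and decided; the decided cell (possibly a dummy or a wrong item)
#' drives the state machine. The task ends when its goal utterances have
#' all been spoken, when a wrong command is spoken (failure), or at the
#' step cap.
#'
#' @param subject A [make_subject_model()].
#' @param model A fitted [fit_swlda()] classifier.
#' @param n_seq Online sequence count.
#' @param task A [task_spec()].
#' @param config A [study_config()].
#' @param chain Filter chain; designed from `config` when `NULL`.
#' @return A `task_result`: list with the selection `log` (tibble),
#'   `selections`, `seconds` (model time: selections x selection duration),
#'   `accuracy`, `completed`, `spoken`, and `spelled_chars`.
#' @export
run_task <- function(subject, model, n_seq, task,
                     config = study_config(), chain = NULL) {
  if (is.null(chain)) chain <- design_filter_chain(config$timing$sample_rate_hz)
  state <- speller_state(config$corpus)
  goals <- trimws(goal_utterances(task))
  log <- list()
  completed <- FALSE
  failed <- FALSE
  step <- 0L
  while (step < config$step_cap) {
    step <- step + 1L
    intent <- simulated_user_policy(state, task)
    if (is.null(intent)) break
    dec <- run_selection(
      subject, model, chain, n_seq, intent$position,
      config$timing,
      seed_tag = substream_seed(task$task_id, "step", step)
    )
    layout <- state$catalog[[state$menu]]
    decided_label <- item_at(layout, dec[1], dec[2])
    res <- apply_selection(state, decided_label)
    state <- res$state
    log[[step]] <- tibble::tibble(
      step = step, menu = res$effects$menu_before,
      intended = intent$label, decided = decided_label,
      correct = identical(
        unname(dec),
        unname(as.integer(intent$position))
      ),
      buffer = state$sentence,
      spoken = paste(res$effects$spoken %||% "", collapse = "; ")
    )
    if (!is.null(res$effects$spoken)) {
      real <- setdiff(
        trimws(res$effects$spoken),
        trimws(command_templates()[["Wait"]])
      )
      if (length(real) > 0 && !all(real %in% goals)) {
        failed <- TRUE # a wrong command went out to the assistant
        break
      }
    }
    if (planning_phase(state, goals) > length(goals)) {
      completed <- TRUE
      break
    }
  }
  log <- dplyr::bind_rows(log)
  structure(
    list(
      task = task,
      log = log,
      selections = nrow(log),
      seconds = nrow(log) * selection_duration(n_seq, config$timing),
      accuracy = if (nrow(log)) mean(log$correct) else NA_real_,
      completed = completed && !failed,
      spoken = state$transcript,
      spelled_chars = task_character_counts(task)$payload_chars
    ),
    class = "task_result"
  )
}

#' @export
print.task_result <- function(x, ...) {
  cat("<task_result> task ", x$task$task_id, ": ", x$selections,
    " selections, ", round(x$seconds, 1), " s, accuracy ",
    round(100 * x$accuracy, 1), "%, ",
    if (x$completed) "completed" else "NOT completed", "\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a no-control wait
#'
#' The subject attends nothing while the NC menu keeps flashing; the wait
#' succeeds if no selection lands on the central IC item. The wait spans
#' `ceiling(duration_s / selection_duration)` selections.
#'
#' @inheritParams run_task
#' @param duration_s Wait length in seconds.
#' @param wait_id Integer tag separating several waits of one subject.
#' @return List with `n_selections`, `escaped` (logical), `escape_step`.
#' @export
simulate_nc_wait <- function(subject, model, n_seq, config = study_config(),
                             chain = NULL, duration_s = 60, wait_id = 1L) {
  if (is.null(chain)) chain <- design_filter_chain(config$timing$sample_rate_hz)
  n_sel <- ceiling(duration_s / selection_duration(n_seq, config$timing))
  escape_step <- NA_integer_
  for (i in seq_len(n_sel)) {
    dec <- run_selection(
      subject, model, chain, n_seq, NULL, config$timing,
      seed_tag = substream_seed(wait_id, "nc-wait", i)
    )
    if (dec[1] == 3L && dec[2] == 3L) { # the central IC cell
      escape_step <- i
      break
    }
  }
  list(
    n_selections = n_sel, escaped = !is.na(escape_step),
    escape_step = escape_step
  )
}

#' Run a full simulated study
#'
#' Calibrates every subject, runs the four tasks in closed loop (plus the
#' two one-minute no-control waits when configured), and assembles a
#' per-subject results table in the reference layout: sequence count,
#' per-task selections and model seconds, totals, minimum actions, and
#' overall accuracy, with subjects under the accuracy threshold flagged.
#'
#' @param config A [study_config()].
#' @return List with `results` (tibble, one row per subject), `summary`
#'   (mean/sd per column), and `nc_waits` (tibble of wait outcomes).
#' @export
run_study <- function(config = study_config()) {
  rows <- list()
  waits <- list()
  for (i in seq_len(config$n_subjects)) {
    subject <- make_subject_model(config$seeds[i], config$difficulties[i])
    cal <- run_calibration(subject, config)
    task_res <- lapply(
      config$tasks,
      function(tk) {
        run_task(subject, cal$model, cal$n_seq, tk, config, cal$chain)
      }
    )
    if (config$nc_waits) {
      for (w in 1:2) {
        wr <- simulate_nc_wait(subject, cal$model, cal$n_seq, config,
          cal$chain,
          wait_id = w
        )
        waits[[length(waits) + 1]] <- tibble::tibble(
          subject = paste0("S", i), wait = w,
          n_selections = wr$n_selections, escaped = wr$escaped
        )
      }
    }
    sel <- vapply(task_res, function(r) r$selections, numeric(1))
    sec <- vapply(task_res, function(r) r$seconds, numeric(1))
    all_log <- dplyr::bind_rows(lapply(task_res, function(r) r$log))
    min_acts <- sum(vapply(
      config$tasks,
      function(tk) length(plan_minimum_actions(tk, corpus = config$corpus)),
      numeric(1)
    ))
    acc <- 100 * mean(all_log$correct)
    rows[[i]] <- tibble::tibble(
      subject = paste0("S", i),
      seed = config$seeds[i],
      difficulty = config$difficulties[i],
      seq = cal$n_seq,
      sel_task1 = sel[1], sel_task2 = sel[2],
      sel_task3 = sel[3], sel_task4 = sel[4],
      sel_total = sum(sel),
      min_actions = min_acts,
      time_task1 = sec[1], time_task2 = sec[2],
      time_task3 = sec[3], time_task4 = sec[4],
      time_total = sum(sec),
      acc = acc,
      completed = all(vapply(task_res, function(r) r$completed, logical(1))),
      excluded = acc < config$accuracy_threshold_pct
    )
  }
  results <- dplyr::bind_rows(rows)
  list(
    results = results,
    summary = summarize_fixture(results),
    nc_waits = if (length(waits)) dplyr::bind_rows(waits) else NULL
  )
}

#' Packaged per-subject online results of the reference study
#'
#' The published table of the original 12-participant online session:
#' chosen sequence count, selections and completion time per task, totals,
#' per-subject minimum action counts, and overall accuracy (%).
#'
#' @return Tibble with one row per subject.
#' @export
reference_online_results <- function() {
  path <- system.file("extdata", "reference_online_results.csv",
    package = "p300speller", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published spelling-part aggregates of the reference study
#'
#' Mean selections and mean time (seconds) spent in the spelling parts
#' (the three tasks with a spelling component), as published; the ratio
#' gives the selections-per-minute figure.
#'
#' @return Tibble with `selections` and `seconds`.
#' @export
reference_spelling_aggregates <- function() {
  tibble::tibble(selections = 65.33, seconds = 1282.89)
}

#' Summarize a results table
#'
#' Column means and standard deviations of every numeric column, plus the
#' selection overhead: the percentage of selections made beyond the
#' error-free minimum,
#' `(mean total selections - mean minimum actions) / mean minimum actions`.
#'
#' @param fixture A results tibble in the layout of
#'   [reference_online_results()] (simulated tables from [run_study()]
#'   work too).
#' @return List with `column_stats` (tibble: `column`, `mean`, `sd`) and
#'   `overhead_pct`.
#' @export
summarize_fixture <- function(fixture) {
  fixture <- tibble::as_tibble(fixture)
  num <- fixture[vapply(fixture, is.numeric, logical(1))]
  if (ncol(num) == 0 || !all(c("sel_total", "min_actions") %in% names(num))) {
    stop("malformed results table: expected the reference column layout",
      call. = FALSE
    )
  }
  stats <- tibble::tibble(
    column = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1))
  )
  list(
    column_stats = stats,
    overhead_pct = 100 *
      (mean(num$sel_total) - mean(num$min_actions)) / mean(num$min_actions)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
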