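test_that("zero-noise calibration yields a perfect curve and the minimum
           sequence count", {
  s <- make_subject_model(41, 0)
  cfg <- study_config(
    n_subjects = 1, seeds = 41, difficulties = 0,
    calibration_word = "DOMO", calibration_n_seq = 3
  )
  cal <- run_calibration(s, cfg)
  expect_true(all(cal$curve$accuracy == 1))
  expect_identical(cal$n_seq, 3L)
  # determinism: the same seed reproduces model and curve exactly
  cal2 <- run_calibration(s, cfg)
  expect_identical(cal$model$selected_features, cal2$model$selected_features)
  expect_identical(cal$curve, cal2$curve)
})

test_that("zero-noise subjects complete the tasks in the minimum number of
           selections", {
  s <- make_subject_model(43, 0)
  cfg <- study_config(
    n_subjects = 1, seeds = 43, difficulties = 0,
    calibration_word = "DOMO", calibration_n_seq = 3
  )
  cal <- run_calibration(s, cfg)
  t1 <- run_task(s, cal$model, cal$n_seq, task_spec(1), cfg, cal$chain)
  expect_identical(t1$selections, 19L)
  expect_equal(t1$accuracy, 1)
  expect_true(t1$completed)
  expect_equal(t1$seconds, 19 * selection_duration(cal$n_seq, cfg$timing))
  t2 <- run_task(s, cal$model, cal$n_seq, task_spec(2), cfg, cal$chain)
  expect_identical(t2$selections, 2L)
  expect_true(t2$completed)
})

test_that("model time bookkeeping: 19 selections at 3 sequences is 178.75 s", {
  expect_equal(19 * selection_duration(3), 178.752, tolerance = 1e-9)
})

test_that("the packaged reference table is self-consistent and matches the
           published aggregates", {
  fx <- reference_online_results()
  expect_identical(nrow(fx), 12L)
  expect_identical(
    fx$sel_total,
    fx$sel_task1 + fx$sel_task2 + fx$sel_task3 + fx$sel_task4
  )
  expect_identical(
    fx$time_total,
    fx$time_task1 + fx$time_task2 + fx$time_task3 + fx$time_task4
  )
  s <- summarize_fixture(fx)
  stat <- function(col) unname(s$column_stats$mean[s$column_stats$column == col])
  expect_equal(round(stat("acc"), 2), 86.14)
  expect_equal(stat("seq"), 4.25)
  expect_equal(round(stat("sel_total"), 2), 82.92)
  expect_equal(round(stat("min_actions"), 2), 61.17)
  expect_equal(s$overhead_pct, 35.5, tolerance = 0.1)
  expect_error(summarize_fixture(fx["seq"]), "malformed")
})

test_that("a small simulated study produces coherent per-subject rows", {
  cfg <- study_config(
    n_subjects = 2, seeds = c(51, 52), difficulties = c(0, 0),
    calibration_word = "DOMO", calibration_n_seq = 3,
    tasks = list(task_spec(2)), nc_waits = FALSE
  )
  # single-task config: totals equal the task column
  st <- run_study(cfg)
  expect_identical(nrow(st$results), 2L)
  expect_identical(st$results$sel_task1, c(2, 2))
  expect_equal(st$results$acc, c(100, 100))
  expect_false(any(st$results$excluded))
  st2 <- run_study(cfg)
  expect_identical(st$results, st2$results)
})

test_that("no-control waits of a zero-noise subject never escape", {
  fit <- cached_fit()
  s0 <- make_subject_model(61, 0)
  wait <- simulate_nc_wait(s0, fit$model, 3, fit$config, fit$chain,
    duration_s = 60
  )
  expect_identical(wait$n_selections, ceiling(60 / selection_duration(3)))
  expect_false(wait$escaped)
})

test_that("online accuracy at the chosen count tracks the calibration curve", {
  # parameter-recovery check across moderate-difficulty subjects; the
  # per-subject curve is estimated from 8 selections (SE ~0.12, so ~0.05
  # for the mean of six), and picking the WSR-argmax count adds a small
  # optimism, hence the 0.15 band (~3 SE) on >200 pooled online decisions
  accs <- c()
  preds <- c()
  for (seed in 71:76) {
    s <- make_subject_model(seed, 0.45)
    cfg <- study_config(
      n_subjects = 1, seeds = seed, difficulties = 0.45,
      calibration_word = "DOMOTICA", calibration_n_seq = 4
    )
    cal <- run_calibration(s, cfg)
    tr <- run_task(s, cal$model, cal$n_seq, task_spec(1), cfg, cal$chain)
    expect_true(tr$completed, label = paste("seed", seed))
    accs <- c(accs, tr$log$correct)
    preds <- c(preds, cal$curve$accuracy[cal$curve$n_seq == cal$n_seq])
  }
  expect_lt(abs(mean(accs) - mean(preds)), 0.15)
})
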