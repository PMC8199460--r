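test_that("subject models are deterministic and difficulty scales the SNR", {
  a <- make_subject_model(1, 0.3)
  b <- make_subject_model(1, 0.3)
  expect_identical(a, b)

  noiseless <- make_subject_model(1, 0)
  expect_identical(noiseless$noise_sigma_uv, 0)

  easy <- make_subject_model(1, 0.2)
  hard <- make_subject_model(1, 0.8)
  ratio <- function(s) s$noise_sigma_uv / max(s$p300_amplitude_uv)
  expect_gt(ratio(hard), ratio(easy))

  expect_error(make_subject_model(1, 1.2), "difficulty")
  expect_error(make_subject_model(1, -0.1), "difficulty")
})

test_that("selection streams superimpose templates additively at zero noise", {
  s <- make_subject_model(5, 0)
  tm <- timing_config()
  sch <- make_flash_schedule(2, seed = 11)
  st <- generate_selection_stream(s, sch, c(0, 0), tm)

  # exactly 2 * n_seq target events: one row flash + one column flash per seq
  expect_identical(sum(st$events$is_target), 2L * 2L)
  expect_identical(nrow(st$events), 28L)
  expect_identical(diff(st$events$onset_sample), rep(56L, 27L))

  # bit-identical determinism for identical inputs
  st0 <- generate_selection_stream(s, sch, c(0, 0), tm)
  expect_identical(st$signal, st0$signal)

  # additivity at zero noise: the signal is exactly the sum of one template
  # per target flash, and attending nothing leaves silence
  st_none <- generate_selection_stream(s, sch, NULL, tm)
  expect_true(all(st_none$signal == 0))
  win <- epoch_samples(tm)
  manual <- matrix(0, nrow(st$signal), ncol(st$signal))
  t_rel <- (seq_len(win) - 1) / tm$sample_rate_hz
  jitter <- p300speller:::with_seed(
    p300speller:::substream_seed(s$seed, "jitter", sch$seed, 0L),
    stats::rnorm(sum(st$events$is_target), 0, s$latency_jitter_s)
  )
  k <- 0
  for (i in which(st$events$is_target)) {
    k <- k + 1
    lat <- s$p300_latency_s + jitter[k]
    bump <- exp(-(t_rel - lat)^2 / (2 * s$template_width_s^2))
    cols <- st$events$onset_sample[i] + seq_len(win)
    manual[, cols] <- manual[, cols] + outer(s$p300_amplitude_uv, bump)
  }
  expect_equal(unname(st$signal), manual, tolerance = 1e-12)
})

test_that("a full selection at 8 sequences yields 16 target flashes", {
  s <- make_subject_model(2, 0.1)
  sch <- make_flash_schedule(8, seed = 1)
  st <- generate_selection_stream(s, sch, c(4, 6))
  expect_identical(sum(st$events$is_target), 16L)
  expect_setequal(
    unique(st$events$stimulus_id[st$events$is_target]),
    c(4L, 13L)
  )
})

test_that("calibration runs have the protocol's epoch and label counts", {
  s <- make_subject_model(4, 0)
  run <- generate_calibration_run(s, "DOMOTICA2021", n_seq = 8)
  expect_identical(n_epochs(run), 12L * 14L * 8L) # 1344
  expect_identical(sum(run$events$is_target), 192L)
  # label conservation: exactly 2/14 of each selection's events are targets
  per_sel <- tapply(run$events$is_target, run$events$selection, mean)
  expect_true(all(per_sel == 2 / 14))

  tiny <- generate_calibration_run(s, "A", n_seq = 1)
  expect_identical(n_epochs(tiny), 14L)
  expect_identical(sum(tiny$events$is_target), 2L)

  expect_error(generate_calibration_run(s, "A?B"), "not present")
})

test_that("pure flash time of the calibration block is ~301 s", {
  tm <- timing_config()
  expect_equal(12 * 14 * 8 * tm$soa_s, 301.056, tolerance = 1e-9)
})

test_that("grand-average target-minus-non-target peaks at 250-500 ms over
           parieto-occipital sites", {
  s <- make_subject_model(8, 0.5)
  run <- generate_calibration_run(s, "AB", n_seq = 8) # 224 epochs
  ga <- grand_average(run)
  diff_po <- ga |>
    dplyr::filter(.data$channel %in% c("Pz", "PO7", "PO8")) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_uv") |>
    dplyr::mutate(d = .data$target - .data$`non-target`)
  peak_ms <- diff_po$time_ms[which.max(diff_po$d)]
  expect_gt(peak_ms, 250)
  expect_lt(peak_ms, 500)
})
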