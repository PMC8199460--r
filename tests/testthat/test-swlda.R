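test_that("a perfect predictor is selected first with the right sign", {
  set.seed(10)
  n <- 200
  y01 <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 5] <- ifelse(y01, 1, -1) + rnorm(n, 0, 1e-3)
  es <- matrix_as_epochs(X, y01)
  m <- fit_swlda(es, swlda_config(max_features = 8))
  expect_true(5 %in% m$selected_features$feature)
  expect_gt(m$selected_features$weight[m$selected_features$feature == 5], 0)
})

test_that("stepwise selection matches an independent naive oracle", {
  cfg <- swlda_config(max_features = 8)
  for (seed in 1:8) {
    set.seed(seed)
    n <- 80
    X <- matrix(rnorm(n * 8), n, 8)
    beta <- c(1.2, 0, 0.8, 0, 0, -0.5, 0, 0)
    y01 <- (X %*% beta + rnorm(n, 0, 1)) > 0
    y01 <- as.vector(y01)
    if (sum(y01) < 2 || sum(!y01) < 2) next
    es <- matrix_as_epochs(X, y01)
    m <- fit_swlda(es, cfg)
    oracle <- naive_stepwise(X, ifelse(y01, 1, -1), max_features = 8)
    expect_identical(sort(m$selected_features$feature), oracle,
      label = paste("seed", seed)
    )
    # weights agree with a plain OLS refit on the final set
    if (length(oracle) > 0) {
      refit <- stats::lm.fit(
        cbind(1, X[, oracle, drop = FALSE]),
        ifelse(y01, 1, -1)
      )
      expect_equal(m$selected_features$weight,
        unname(refit$coefficients[-1]),
        tolerance = 1e-8
      )
    }
  }
})

test_that("the refitted model keeps every feature at p <= p_remove and
           respects the feature cap", {
  fit <- cached_fit()
  cfg <- fit$config$swlda
  m <- fit$model
  expect_lte(nrow(m$selected_features), cfg$max_features)
  # refit consistency
  run <- generate_calibration_run(
    fit$subject, fit$config$calibration_word,
    fit$config$calibration_n_seq,
    filter_chain = fit$chain, run_id = 1L
  )
  X <- p300speller:::flatten_epochs(run)[, m$selected_features$feature,
    drop = FALSE
  ]
  y <- ifelse(run$events$is_target, 1, -1)
  pv <- p300speller:::included_pvalues(X, y)$p
  expect_true(all(pv <= cfg$p_remove + 1e-12))
})

test_that("scoring is affine in the epoch and errors on shape mismatch", {
  fit <- cached_fit()
  m <- fit$model
  d <- c(m$training_meta$n_channels, m$training_meta$n_samples)
  zero <- matrix(0, d[1], d[2])
  expect_identical(score_epoch(m, zero), m$intercept)
  set.seed(2)
  x <- matrix(rnorm(prod(d)), d[1], d[2])
  expect_equal(
    score_epoch(m, 3 * x) - m$intercept,
    3 * (score_epoch(m, x) - m$intercept),
    tolerance = 1e-10
  )
  expect_error(score_epoch(m, matrix(0, 2, 5)), "shape")
})

test_that("zero-noise target epochs outscore every non-target epoch", {
  s <- make_subject_model(21, 0)
  train <- generate_calibration_run(s, "AB1", n_seq = 2, run_id = 1L)
  m <- fit_swlda(train)
  test <- generate_calibration_run(s, "XY9", n_seq = 2, run_id = 2L)
  sc <- score_epochs(m, test)
  expect_gt(min(sc[test$events$is_target]), max(sc[!test$events$is_target]))
})

test_that("single-class input is rejected", {
  s <- make_subject_model(1, 0.3)
  run <- generate_calibration_run(s, "A", n_seq = 2)
  only_nt <- run
  only_nt$events$is_target <- FALSE
  expect_error(fit_swlda(only_nt), "each class")
})

test_that("accuracy-by-sequences is 1 at every k for a zero-noise subject
           and errors beyond the available sequences", {
  s <- make_subject_model(31, 0)
  train <- generate_calibration_run(s, "AB", n_seq = 2, run_id = 1L)
  m <- fit_swlda(train)
  run <- generate_calibration_run(s, "CD2", n_seq = 4, run_id = 2L)
  curve <- accuracy_by_sequences(m, run)
  expect_identical(curve$n_seq, 1:4)
  expect_true(all(curve$accuracy == 1))
  expect_error(accuracy_by_sequences(m, run, seq_range = 5), "exceeds")
})
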