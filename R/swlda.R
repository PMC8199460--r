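# Stepwise linear discriminant analysis (SWLDA), the classical P300 decoder:
# ordinary least squares of coded class labels on (channel, sample) features,
# with iterative forward inclusion (smallest coefficient p-value < p_enter)
# and backward elimination (every included feature with p-value > p_remove),
# capped at a maximum model size. Forward candidate p-values are computed
# from partial correlations on residuals kept orthogonal to the included
# set, which is algebraically identical to refitting the OLS model with the
# candidate added.

#' SWLDA configuration
#'
#' Defaults follow the standard P300 classifier settings: at most 60
#' features, inclusion below p = 0.1, exclusion above p = 0.15.
#'
#' @param max_features Maximum number of selected features.
#' @param p_enter Forward-inclusion p-value threshold, in (0, 1).
#' @param p_remove Backward-elimination p-value threshold; must exceed
#'   `p_enter` (the usual stepwise stability condition).
#' @param label_coding Length-2 numeric codes for (non-target, target).
#' @param standardize Z-score features before fitting (off by default,
#'   matching the regression-on-raw-signals formulation).
#' @return An `swlda_config` list.
#' @export
swlda_config <- function(max_features = 60, p_enter = 0.1, p_remove = 0.15,
                         label_coding = c(-1, 1), standardize = FALSE) {
  stopifnot(
    max_features >= 1, p_enter > 0, p_enter < 1,
    p_remove > 0, p_remove < 1, length(label_coding) == 2,
    label_coding[1] != label_coding[2]
  )
  if (p_enter >= p_remove) {
    stop("`p_enter` must be smaller than `p_remove`", call. = FALSE)
  }
  structure(
    list(
      max_features = as.integer(max_features), p_enter = p_enter,
      p_remove = p_remove, label_coding = label_coding,
      standardize = isTRUE(standardize)
    ),
    class = "swlda_config"
  )
}

# OLS p-values for the currently included columns (intercept always present).
# Aliased (rank-deficient) columns are reported with p = 1 so the backward
# step discards them.
included_pvalues <- function(X_inc, y) {
  Xd <- cbind(1, X_inc)
  k <- ncol(X_inc)
  qrX <- qr(Xd)
  coef <- qr.coef(qrX, y)
  aliased <- is.na(coef)
  coef[aliased] <- 0
  res <- y - Xd %*% coef
  rss <- sum(res^2)
  df <- length(y) - qrX$rank
  if (df <= 0 || rss <= max(sum(y^2), 1) * 1e-12) {
    p <- rep(0, k)
    p[aliased[-1]] <- 1
    return(list(p = p, coef = coef, rss = rss))
  }
  sigma2 <- rss / df
  Rm <- qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE]
  dvals <- rep(NA_real_, ncol(Xd))
  dvals[qrX$pivot[seq_len(qrX$rank)]] <- diag(chol2inv(Rm))
  se <- sqrt(sigma2 * dvals)
  tval <- coef / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[aliased] <- 1
  list(p = as.numeric(p[-1]), coef = coef, rss = rss)
}

#' Fit an SWLDA classifier on labeled epochs
#'
#' Features are the flattened (channel, sample) cells of each epoch,
#' channel-major. Labels are coded per `config$label_coding` and regressed
#' by OLS; features enter one at a time (smallest p-value below `p_enter`,
#' ties to the lowest feature index), then every included feature whose
#' p-value in the refitted model exceeds `p_remove` is removed. Iteration
#' stops when the model no longer changes, the feature cap is reached, or
#' the residual is numerically exhausted.
#'
#' @param epochs A labeled [epoch_set()] (needs `events$is_target` with both
#'   classes present).
#' @param config An [swlda_config()].
#' @return An `swlda_model` with `selected_features` (tibble: `feature`,
#'   `channel`, `sample`, `time_ms`, `weight`), `intercept`, and
#'   `training_meta`.
#' @export
fit_swlda <- function(epochs, config = swlda_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  y01 <- epochs$events$is_target
  if (length(unique(y01)) < 2 || sum(y01) < 2 || sum(!y01) < 2) {
    stop("need at least two epochs of each class to fit SWLDA",
      call. = FALSE
    )
  }
  X <- flatten_epochs(epochs)
  if (config$standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  y <- ifelse(y01, config$label_coding[2], config$label_coding[1])
  n <- nrow(X)
  p <- ncol(X)

  # Orthogonalized state: Q spans {1} U included columns; R holds candidate
  # columns with the Q-projection removed, res_y the label residual.
  q0 <- rep(1 / sqrt(n), n)
  res_y <- y - q0 * sum(q0 * y)
  R <- X - tcrossprod(q0, colSums(X) / sqrt(n))
  norms2 <- colSums(R^2)
  tss <- sum(res_y^2)
  included <- integer(0)
  active <- norms2 > max(norms2, 1) * 1e-12 # drop constant columns

  rebuild <- function(inc) {
    Q <- qr.Q(qr(cbind(1, X[, inc, drop = FALSE])))
    res_y <<- y - Q %*% crossprod(Q, y)
    R <<- X - Q %*% crossprod(Q, X)
    norms2 <<- colSums(R^2)
  }

  seen <- character(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(included) < config$max_features && sum(res_y^2) > tss * 1e-10) {
      rss_y <- sum(res_y^2)
      cand <- active & norms2 > 1e-10
      cand[included] <- FALSE
      if (any(cand)) {
        ry <- as.vector(crossprod(R[, cand, drop = FALSE], res_y))
        r <- ry / sqrt(norms2[cand] * rss_y)
        r <- pmin(pmax(r, -1), 1)
        df <- n - length(included) - 2
        pv <- rep(1, sum(cand))
        ok <- df > 0
        if (ok) {
          denom <- pmax(1 - r^2, 1e-15)
          tv <- r * sqrt(df) / sqrt(denom)
          pv <- 2 * stats::pt(-abs(tv), df)
        }
        best <- which.min(pv) # ties: which.min takes the first = lowest index
        if (pv[best] < config$p_enter) {
          j <- which(cand)[best]
          q <- R[, j] / sqrt(norms2[j])
          a <- as.vector(crossprod(R, q))
          res_y <- res_y - q * sum(q * res_y)
          R <- R - tcrossprod(q, a)
          norms2 <- pmax(norms2 - a^2, 0)
          included <- c(included, j)
          changed <- TRUE
        }
      }
    }
    # backward step: drop every included feature with p > p_remove
    if (length(included) > 1) {
      ip <- included_pvalues(X[, included, drop = FALSE], y)
      drop <- ip$p > config$p_remove
      if (any(drop)) {
        included <- included[!drop]
        rebuild(included)
        changed <- TRUE
      }
    }
    sig <- paste(sort(included), collapse = ",")
    if (!changed || sig %in% seen) break # stable, or a cycle guard tripped
    seen <- c(seen, sig)
  }

  included <- sort(included)
  fit <- stats::lm.fit(cbind(1, X[, included, drop = FALSE]), y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  d <- dim(epochs$epochs)
  cs <- feature_index_to_cs(included, d[3])
  feats <- tibble::tibble(
    feature = included,
    channel = epochs$channel_names[cs$channel],
    channel_index = cs$channel,
    sample = cs$sample,
    time_ms = (cs$sample - 1) / epochs$timing$sample_rate_hz * 1000 +
      epochs$timing$epoch_window_s[1] * 1000,
    weight = as.numeric(coefs[-1])
  )
  structure(
    list(
      selected_features = feats,
      intercept = as.numeric(coefs[1]),
      training_meta = list(
        config = config, n_epochs = n, n_features_total = p,
        n_channels = d[2], n_samples = d[3],
        rss = sum(fit$residuals^2), tss = tss,
        sample_rate_hz = epochs$timing$sample_rate_hz
      )
    ),
    class = "swlda_model"
  )
}

#' @export
print.swlda_model <- function(x, ...) {
  cat("<swlda_model> ", nrow(x$selected_features), " features, intercept ",
    signif(x$intercept, 4), ", trained on ", x$training_meta$n_epochs,
    " epochs\n",
    sep = ""
  )
  invisible(x)
}

#' Score epochs with an SWLDA model
#'
#' The score of an epoch is `intercept + sum(weight_i * epoch[feature_i])`,
#' linear in the epoch; higher scores indicate the attended (target) class.
#'
#' @param model An [fit_swlda()] model.
#' @param epoch A channels x samples matrix matching the training shape.
#' @return A single numeric score.
#' @export
score_epoch <- function(model, epoch) {
  meta <- model$training_meta
  if (!is.matrix(epoch) || nrow(epoch) != meta$n_channels ||
    ncol(epoch) != meta$n_samples) {
    stop("epoch shape (", paste(dim(epoch), collapse = " x "),
      ") does not match training shape (", meta$n_channels, " x ",
      meta$n_samples, ")",
      call. = FALSE
    )
  }
  f <- model$selected_features
  model$intercept + sum(f$weight * epoch[cbind(f$channel_index, f$sample)])
}

#' Score every epoch of an epoch set
#'
#' @param model An [fit_swlda()] model.
#' @param epochs An [epoch_set()].
#' @return Numeric vector of scores, one per epoch.
#' @export
score_epochs <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  meta <- model$training_meta
  if (d[2] != meta$n_channels || d[3] != meta$n_samples) {
    stop("epoch shape does not match training shape", call. = FALSE)
  }
  f <- model$selected_features
  if (nrow(f) == 0) {
    return(rep(model$intercept, d[1]))
  }
  vals <- vapply(
    seq_len(nrow(f)),
    function(i) epochs$epochs[, f$channel_index[i], f$sample[i]],
    numeric(d[1])
  )
  model$intercept + as.vector(matrix(vals, nrow = d[1]) %*% f$weight)
}

#' Selection accuracy as a function of sequence count
#'
#' Re-decides every selection of a labeled run using only its first `k`
#' sequences of flashes (truncation semantics) and reports the fraction of
#' correct decisions for each `k`, reproducing the calibration
#' accuracy-versus-sequences curve.
#'
#' @param model An [fit_swlda()] model.
#' @param run A labeled [epoch_set()] whose events carry `selection`,
#'   `attended_row` and `attended_col`, with complete selections at the
#'   maximum sequence count.
#' @param seq_range Integer vector of sequence counts to evaluate.
#' @return An `accuracy_curve`: tibble with `n_seq` and `accuracy`.
#' @export
accuracy_by_sequences <- function(model, run, seq_range = NULL) {
  stopifnot(inherits(run, "epoch_set"))
  ev <- run$events
  stopifnot(all(c("selection", "attended_row", "attended_col") %in% names(ev)))
  scores <- score_epochs(model, run)
  sel_ids <- unique(ev$selection)
  n_flashes <- nrow(ev) / length(sel_ids)
  k_max <- n_flashes / 14
  if (is.null(seq_range)) seq_range <- seq_len(k_max)
  if (any(seq_range > k_max)) {
    stop("requested sequence count exceeds the ", k_max,
      " sequences available",
      call. = FALSE
    )
  }
  acc <- vapply(seq_range, function(k) {
    correct <- vapply(sel_ids, function(s) {
      idx <- which(ev$selection == s)[seq_len(14 * k)]
      dec <- decide_item(scores[idx], ev$stimulus_id[idx])
      dec[1] == ev$attended_row[idx[1]] && dec[2] == ev$attended_col[idx[1]]
    }, logical(1))
    mean(correct)
  }, numeric(1))
  structure(
    tibble::tibble(n_seq = as.integer(seq_range), accuracy = acc),
    class = c("accuracy_curve", "tbl_df", "tbl", "data.frame")
  )
}
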