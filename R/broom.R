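# broom-style accessors for the fitted classifier.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected features of an SWLDA model
#'
#' @param x An [fit_swlda()] model.
#' @param ... Ignored.
#' @return Tibble with one row per selected (channel, time) feature:
#'   `channel`, `time_ms`, `weight`.
#' @export
tidy.swlda_model <- function(x, ...) {
  dplyr::select(
    x$selected_features,
    "channel", "time_ms", "weight"
  )
}

#' One-row summary of an SWLDA model
#'
#' @param x An [fit_swlda()] model.
#' @param ... Ignored.
#' @return Tibble with `n_features`, `n_epochs`, `r_squared` (of the label
#'   regression), `max_features`, `p_enter`, `p_remove`.
#' @export
glance.swlda_model <- function(x, ...) {
  meta <- x$training_meta
  tibble::tibble(
    n_features = nrow(x$selected_features),
    n_epochs = meta$n_epochs,
    r_squared = 1 - meta$rss / meta$tss,
    max_features = meta$config$max_features,
    p_enter = meta$config$p_enter,
    p_remove = meta$config$p_remove
  )
}
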