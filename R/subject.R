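# Generative model of one simulated participant. The P300 is modelled as a
# per-channel scaled Gaussian bump added to ongoing noise after every attended
# flash; a single `difficulty` knob trades ERP amplitude against noise power.

#' EEG channel montage used throughout the package
#'
#' Eight parieto-central/occipital positions of the 10/20 system.
#' @return Character vector of channel names.
#' @export
speller_channels <- function() {
  c("Fz", "Cz", "Pz", "Oz", "P3", "P4", "PO7", "PO8")
}

# Relative P300 topography: strongest over parieto-occipital sites.
.p300_topography <- c(
  Fz = 2, Cz = 3, Pz = 5, Oz = 4, P3 = 3.5, P4 = 3.5, PO7 = 5, PO8 = 5
)

#' Create a simulated participant
#'
#' Builds the generative parameters of one subject. `difficulty` interpolates
#' between a noiseless ideal responder (0) and a signal-free recording (1):
#' ERP amplitudes are scaled by `1 - difficulty` while the noise standard
#' deviation grows as `noise_base_uv * difficulty`, so the noise-to-amplitude
#' ratio is strictly increasing in `difficulty`. Subject-specific latency and
#' amplitude variation is drawn deterministically from `seed`.
#'
#' @param seed Integer seed; all of this subject's randomness (latency
#'   draw, later noise and jitter streams) derives from it.
#' @param difficulty Number in `[0, 1]`.
#' @param amplitude_uv Named per-channel peak amplitudes in microvolts before
#'   difficulty scaling; defaults peak at 5 uV over Pz/PO7/PO8.
#' @param latency_s P300 peak latency in seconds, in `[0.25, 0.5]`. When
#'   `NULL` (default) it is drawn uniformly in 0.30--0.40 s from `seed`.
#' @param latency_jitter_s Standard deviation of per-flash latency jitter.
#' @param template_width_s Gaussian template width (standard deviation), s.
#' @param noise_base_uv Noise standard deviation at `difficulty = 1`, in uV.
#' @param noise_spectrum `"white"` or `"one_over_f"`.
#' @return A `subject_model` object.
#' @examples
#' s <- make_subject_model(seed = 1, difficulty = 0.3)
#' s$noise_sigma_uv
#' @export
make_subject_model <- function(seed,
                               difficulty,
                               amplitude_uv = NULL,
                               latency_s = NULL,
                               latency_jitter_s = 0.02,
                               template_width_s = 0.06,
                               noise_base_uv = 30,
                               noise_spectrum = c("white", "one_over_f")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!is.numeric(difficulty) || length(difficulty) != 1 ||
      is.na(difficulty) || difficulty < 0 || difficulty > 1) {
    stop("`difficulty` must be a number in [0, 1]", call. = FALSE)
  }
  noise_spectrum <- match.arg(noise_spectrum)
  stopifnot(latency_jitter_s >= 0, template_width_s > 0)
  if (latency_jitter_s >= template_width_s) {
    stop("`latency_jitter_s` must be smaller than `template_width_s`",
      call. = FALSE
    )
  }
  channels <- speller_channels()
  if (is.null(amplitude_uv)) {
    scale <- with_seed(
      substream_seed(seed, "subject", "amplitude"),
      stats::runif(1, 0.9, 1.1)
    )
    amplitude_uv <- .p300_topography * scale
  }
  stopifnot(all(amplitude_uv >= 0))
  amplitude_uv <- amplitude_uv[channels]
  if (is.null(latency_s)) {
    latency_s <- with_seed(
      substream_seed(seed, "subject", "latency"),
      stats::runif(1, 0.30, 0.40)
    )
  }
  stopifnot(latency_s >= 0.25, latency_s <= 0.5)
  structure(
    list(
      seed = as.integer(seed),
      difficulty = difficulty,
      p300_amplitude_uv = amplitude_uv * (1 - difficulty),
      p300_latency_s = latency_s,
      latency_jitter_s = latency_jitter_s,
      template_width_s = template_width_s,
      noise_sigma_uv = noise_base_uv * difficulty,
      noise_spectrum = noise_spectrum,
      channel_names = channels
    ),
    class = "subject_model"
  )
}

#' @export
print.subject_model <- function(x, ...) {
  cat("<subject_model> seed ", x$seed,
    ", difficulty ", signif(x$difficulty, 3),
    ", peak ", signif(max(x$p300_amplitude_uv), 3), " uV @ ",
    round(x$p300_latency_s * 1000), " ms, noise sigma ",
    signif(x$noise_sigma_uv, 3), " uV (", x$noise_spectrum, ")\n",
    sep = ""
  )
  invisible(x)
}
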