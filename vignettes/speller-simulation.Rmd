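---
title: "Simulating an asynchronous P300 row–column speller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an asynchronous P300 row-column speller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300speller)
```

## The system being simulated

A P300 speller presents a 7×7 matrix whose rows and columns flash in
pseudo-random order (a *row–column paradigm*). The user attends one cell
and counts its flashes; attended flashes elicit a P300 — a positive
event-related potential over parieto-occipital sites roughly 250–500 ms
after stimulus onset. Summing classifier scores per row and per column
over a few *sequences* (one sequence = each of the 14 stimuli once) and
taking the argmax of each identifies the attended cell.

Here the speller composes voice commands for a phone assistant across
four menus: **NC** (no control: 48 dummies around one central `IC` cell,
so a resting user exits only with probability 1/49 per selection), **IC**
(ten commands: four send, three read, Reply, Cancel, NC), **Spelling**
(26 letters + 10 digits, seven word-prediction slots, space/comma,
character and word deletion, OK, IC) and **Confirmation** (Confirm/Back),
guarding the buffer-clearing selections. Everything — timing, menus,
classifier, metrics — runs in simulation; no hardware or audio exists,
and spoken commands are strings in a transcript.

## Signal model

One selection is generated as a **continuous multichannel stream**, not as
independent epochs: with a 224 ms stimulus onset asynchrony and a 0–800 ms
analysis window, consecutive epochs share 144 of their 200 samples, and a
target flash bleeds into the windows of its neighbors. Generating the
stream first and cutting epochs afterwards reproduces exactly the overlap
structure the online system faces.

Each attended flash adds a Gaussian bump
`A_c * exp(-(t - L)^2 / (2 w^2))` on channel `c`, with defaults chosen as
round numbers in the physiological range: peak amplitude 5 µV on
Pz/PO7/PO8 (smaller frontally, reflecting the P300 topography), latency
`L` drawn once per subject from 0.30–0.40 s (within the canonical
250–500 ms window), per-flash latency jitter 20 ms (SD), and template
width `w` = 60 ms (SD). Non-target flashes add nothing by default; an
early visual component is deliberately not modeled. Ongoing noise is
Gaussian white (a 1/f-amplitude option exists); band-limiting is left to
the preprocessing chain, as online.

A single `difficulty` knob `d` in [0, 1] scales amplitudes by `1 − d` and
sets the noise SD to `30 d` µV, so `d = 0` is exactly noiseless, `d = 1`
is exactly signal-free (chance-level by construction), and the
noise-to-signal ratio is strictly increasing in `d`. The 30 µV ceiling was
fixed by matching the *shape* of a mid-difficulty calibration curve to the
reference behavior of real participants — accuracies crossing 70–90%
around 2–3 sequences and saturating near 5 — with difficulty 0.5 giving
a 15 µV noise SD against a ~2.5 µV template peak. All randomness flows
from one per-subject seed through named substreams (subject parameters,
schedules, noise, jitter), so every run is bit-reproducible.

What the generator does **not** emulate: eye blinks, EMG, electrode
drift, alpha rhythm, non-stationarity, or attention lapses. Passing tests
therefore demonstrate correctness of the pipeline and realistic
*relative* behavior (accuracy versus sequences, chance levels), not
absolute performance parity with any human cohort.

## Preprocessing

The online chain is: first-order IIR high-pass at 0.1 Hz, second-order
Butterworth low-pass at 9 Hz, and a 50 Hz notch realized as an order-3
Chebyshev type-I band-stop — two third-order sections in pole count. The
notch's ripple (0.5 dB) and stopband edges (48–52 Hz) are not dictated by
the protocol and are exposed as arguments; tests assert only attenuation
contracts (DC blocked, ≥20 dB extra attenuation at 50 Hz relative to
5 Hz, mid-band within 3 dB). Filtering is **causal** (single pass) by
default to mirror online operation; a `zero_phase` flag enables two-pass
filtering for offline work. Feature decimation before classification is
available but off by default. No artifact rejection is applied, matching
the reference system.

A note on stability testing: the 0.1 Hz high-pass pole has a ~1.6 s time
constant (~400 samples at 250 Hz), so its impulse response cannot decay
to 10⁻⁶ of peak within a couple of thousand samples; the stability test
asserts that decay at a horizon of many time constants (beyond sample
15000) together with a monotonically shrinking envelope.

## SWLDA classifier

Features are the raw (channel, sample) cells of each 8×200 epoch,
flattened channel-major (1600 candidates). Labels are coded −1/+1
(configurable) and fitted by ordinary least squares. Selection is the
classical stepwise procedure: **forward**, add the excluded feature with
the smallest coefficient p-value below 0.1 (ties to the lowest feature
index, for determinism); **backward**, refit and drop every included
feature whose p-value exceeds 0.15; stop when nothing changes or 60
features are included. Forward candidate p-values come from partial
correlations of residuals kept orthogonal to the included set — exactly
the t-test of the candidate's coefficient in the refitted model, at a
fraction of the cost. Degenerate candidates (numerically collinear with
the included set) are skipped; a residual that is numerically exhausted
stops the forward phase (relevant for noiseless subjects); aliased
columns in a backward refit are treated as removable. A signature check
on the included set guards against cycling. No feature standardization is
applied by default, matching the regression-on-raw-signals formulation;
a z-scoring flag exists.

The test suite holds this implementation against an independently written
naive stepwise routine that refits `lm()` for every candidate at every
step, on problems small enough to enumerate.

## Sequence choice and metrics

Calibration fits the classifier on 12 selections at 8 sequences, then
re-decides a fresh simulated run truncated to k = 1…8 sequences to get
the accuracy curve. The online count maximizes the **written symbol
rate**, `WSR = (2 SR − 1)/T` for `SR > 0.5` and 0 otherwise, with
`SR = B/log2 N` and `B` the Wolpaw bits per selection (with the
continuity convention `0 log 0 = 0`); ties go to the smaller count and
the result is clamped below at three, as in the protocol. `T` is the pure
flash time `14 k × 0.224 s` unless a pause is configured — the reference
study does not state which convention its online ITR used, so `itr()`
takes `T` explicitly and the package asserts nothing about that printed
mean. Study-level summaries average per-subject values (mean of ratios,
not ratio of means), matching the published OCM definition.

## Planning and the simulated user

Minimum action counts are computed by breadth-first search over the real
state machine, with two safe prunings: buffers that are not a prefix of
the goal utterance, and wrongly spoken commands, cannot lie on a shortest
path. Prediction slots are resolved against the corpus at every state, so
a plan may type `F`, take the `FRANCISCO` completion, and so on. Selecting
a prediction appends a trailing space — without that convention the
published 19-action minimum for the WhatsApp task is not achievable, and
it matches common speller predictors. The packaged corpus is constructed
so the published prediction offsets hold (receiver after one character,
the two long words after three and two, the mail receiver after two) and
no earlier shortcut exists; higher-frequency decoys fill the earlier
prefixes.

The simulated user follows the current plan and, after a wrong selection,
repairs before replanning: a wrong character gets `Del.`, a wrong
completed word `Del. W`, an unintended Confirmation menu `Back`, and a
buffer whose fixed command prefix is wrong is abandoned through
`IC` → `Confirm`. Free-text parts (the Telegram reply, the e-mail body)
default to fixed fixture strings ("PASTA", "HOLA PAULA FELIZ NAVIDAD") so
runs are deterministic; both are configurable. The two one-minute NC waits
are simulated as ⌈60 s / selection duration⌉ selections of a non-attending
(noise-only) user.

## Numerical and design choices

* Decisions break ties toward the lowest stimulus id; with continuous
  noise, ties have measure zero.
* Summed per-stimulus scores decide selections; this is algebraically the
  same as scoring per-stimulus average epochs with any linear model, and
  a test verifies the identity numerically.
* Epoch windows are closed on the left: an event at sample 0 takes
  samples 0–199.
* `Del.` on an empty buffer is a no-op; deletions never reach into the
  fixed command prefix.
* Model time (selections × selection duration) replaces wall time
  everywhere; published per-task times include human pauses a simulator
  cannot reproduce, so no timing comparison against the reference table
  is made.
* Problem sizes in the test suite are the package's own choice for a
  compact default run: reduced calibrations (8 characters × 4 sequences)
  where only *a* trained model is needed, the full 12 × 8 protocol where
  protocol counts matter (1344 epochs, 192 targets), 5000 Monte-Carlo
  selections for the chance-level check, and 20 subjects for the
  monotonicity property.

## Known limitations

The noise model is stationary and white by default; real EEG is colored
and non-stationary, and real calibration-to-online drops can be larger
than the simulated ones. The word predictor is a plain frequency-prefix
model over a tiny fixture corpus. The virtual assistant is represented
only by the command strings it would receive; its misrecognition behavior
is documented in the reference study but deliberately not modeled.
Questionnaire scoring functions (SUS, Raw NASA-TLX) are provided, but no
subjective data is simulated.
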