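# p300speller

A desk-scale simulator of an asynchronous **P300 row–column speller** that
drives smartphone messaging through spoken virtual-assistant commands.

Severely motor-impaired users can lose every muscular communication
channel; a visual P300 brain–computer interface restores one by flashing
the rows and columns of a 7×7 menu while the user silently counts the
flashes of the item they want. The attended flashes elicit a parieto-
occipital positivity ~250–500 ms after stimulus onset; a linear classifier
trained on a short calibration block detects it and the speller selects
the cell at the intersection of the best row and best column. Composed
sentences such as *"Ok Google, send a WhatsApp to FRANCISCO …"* are handed
to a phone's voice assistant, which does the actual messaging.

This package re-creates that whole loop **without hardware**, for method
study, protocol planning and teaching:

* **Synthetic EEG** — 8 channels (Fz, Cz, Pz, Oz, P3, P4, PO7, PO8) at
  250 Hz; flashes every 224 ms (192 ms stimulus duration); each attended
  flash adds a per-channel scaled Gaussian P300 template on ongoing noise,
  generated as one continuous stream so the 0–800 ms analysis windows
  overlap exactly as they do online. A single `difficulty` knob spans
  noiseless (0) to signal-free (1) subjects.
* **Online preprocessing** — 0.1 Hz first-order IIR high-pass, 9 Hz
  second-order Butterworth low-pass, 50 Hz Chebyshev notch; causal
  single-pass filtering; 200-sample epoch extraction.
* **SWLDA** — stepwise linear discriminant analysis on the flattened
  (channel, sample) features: ordinary least squares of coded labels with
  forward inclusion at p < 0.1, backward elimination at p > 0.15, at most
  60 features.
* **Row–column engine** — pseudo-random permutation flash schedules, score
  accumulation per stimulus, argmax row/column decision.
* **Four-menu state machine** — No-Control (rest; 1/49 chance exit),
  Intentional-Control (ten commands), Spelling (36 characters, 7
  word-prediction slots, corrections, OK/IC) and Confirmation, with
  voice-command composition and a frequency-corpus word predictor.
* **Planning and simulated users** — breadth-first minimum-action planning
  over the state machine and an error-aware user policy that repairs
  mistakes (delete character/word, back out of menus) and replans.
* **Metrics** — accuracy, bits/selection, information transfer rate,
  (written) symbol rate, output characters per minute, WSR-based sequence
  choice with a floor of three, SUS and Raw NASA-TLX scoring.
* **Reference data** — the published per-subject online results of the
  original 12-participant study ship as a plain-CSV fixture for summary
  reproduction.

## Worked example

```r
library(p300speller)

# a moderate-difficulty simulated participant
subject <- make_subject_model(seed = 7, difficulty = 0.5)
config  <- study_config(n_subjects = 1, seeds = 7, difficulties = 0.5)

# calibration: 12 selections ("DOMOTICA2021") at 8 sequences -> SWLDA
cal <- run_calibration(subject, config)
cal$curve
#> # A tibble: 8 × 2
#>   n_seq accuracy
#>   <int>    <dbl>
#> 1     1    0.5
#> 2     2    0.833
#> 3     3    0.75
#> 4     4    0.833
#> 5     5    1
#> 6     6    1
#> 7     7    1
#> 8     8    1
cal$n_seq
#> [1] 3

# the accuracy climbs with the number of stimulation sequences; the chosen
# online count maximizes the written symbol rate, never below 3.

# closed-loop WhatsApp task (send "EXPERIMENTO EN LA UNIVERSIDAD" to
# FRANCISCO); the planner's error-free minimum is 19 selections
length(plan_minimum_actions(task_spec(1)))
#> [1] 19
tr <- run_task(subject, cal$model, cal$n_seq, task_spec(1), config, cal$chain)
tr
#> <task_result> task 1: 36 selections, 338.7 s, accuracy 75%, completed
# at 75% selection accuracy the simulated user needed 36 selections to land
# the 19-action plan: every error costs a correction, much as the reference
# cohort's ~36% selection overhead

# headline metrics at the published mean accuracy
bits_per_selection(0.8614, 49)   # bits per selection
#> [1] 4.260073
summarize_fixture(reference_online_results())$overhead_pct
#> [1] 35.55858
```

`tidy()` and `glance()` expose the fitted classifier's selected
(channel, time) features and fit statistics; `autoplot()` draws the
calibration curve and the target/non-target grand-average waveforms.

## Not modeled

Real EEG acquisition and amplifier interop, eye gaze and artifacts,
text-to-speech audio, and the assistant's speech-misrecognition behavior
are out of scope; voice commands are produced as strings only.
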