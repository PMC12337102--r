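# ecodec

Decoding attempted speech from sensorimotor electrocorticography (ECoG),
with specificity to volitional speech during reading and listening.

`ecodec` is aimed at neural-engineering researchers who want a desk-scale,
fully reproducible implementation of a speech-neuroprosthesis decoding stack:

* **features** — common-average referencing; high-gamma amplitude (HGA,
  70–150 Hz envelope) and low-frequency signal (LFS, 1–100 Hz) at 200 Hz;
  causal 30 s sliding z-score; trial baseline z-score; variance-suppression
  artifact screening.
* **simulate** — a seeded generator of sensorimotor-ECoG feature streams
  with ground-truth electrode classes (shared / articulatory / auditory /
  visual / silent), task-evoked responses ordered speech > reading >
  listening at shared electrodes, pre-go-cue planning ramps, per-word tuning,
  and theta/beta oscillations suppressed during attempted speech.
* **detect** — a strictly causal 3-layer LSTM emitting 200 Hz probabilities
  over {silence, preparation, speech, reading, listening}; smoothing +
  probability threshold θ_p + time thresholds T_on/T_off (0.5 s) turn the
  speech probability into discrete events with onset d\*.
* **verify** — an ensemble of conv + GRU classifiers over a 4 s window
  around d\* that accepts an event as attempted speech only when the mean
  speech probability exceeds 0.65.
* **classify** — conv + GRU ensembles mapping verified windows onto a
  10-word vocabulary; time-window retraining ([−2,0], [−1,1], [0,2] s around
  the go-cue) with shared/articulatory electrode ablations; cross-task
  transfer.
* **evaluate** — event matching within 0.5 s (duplicates counted once),
  TPR/FPR, pseudo-blocks, stratified 10-fold cross-validation with per-fold
  ensembles, Fisher exact / Holm–Bonferroni / permutation correlations.
* **mapping** — rank-sum electrode responsiveness with Holm correction,
  shared-electrode sets, gradient-based electrode contribution maps,
  multitaper theta (5–12 Hz) / beta (20–30 Hz) power contrasts, and
  longform-activation tests.

The recurrent networks (LSTM, GRU, temporal convolution, with exact backward
passes) are implemented in C++/RcppArmadillo; no deep-learning framework is
required, and training is bit-reproducible on CPU from a single seed.

## Worked example

Train two speech detectors on a simulated isolated-target session — one that
has seen reading/listening examples and one trained on speech data only —
then count detections on a listening-only block where the user never
attempts to speak:

```r
library(ecodec)

train <- simulate_session(sim_config(
  n_electrodes = 12,
  schedule = list(type = "isolated_target",
                  task = c("speech", "reading", "listening"), n_trials = 36),
  seed = 1))

hy <- detector_hyper(hidden = 24, epochs = 18, lr = 2e-3, batch_size = 16)
det <- fit_detector(train, hyper = hy, seed = 1)
det_speech_only <- fit_detector(train, hyper = hy,
                                class_subset = c("silence", "preparation",
                                                 "speech"),
                                seed = 1)

# longform listening block: a podcast plays, no speech attempts occur
lf <- simulate_session(sim_config(
  n_electrodes = 12,
  schedule = list(type = "longform", condition = "listening", duration = 90),
  seed = 51))
cat(sprintf("full detector: %d detections; speech-only detector: %d detections\n",
            nrow(detect_events(det, lf)), nrow(detect_events(det_speech_only, lf))))
#> full detector: 0 detections; speech-only detector: 17 detections
```

Every one of the speech-only detector's 17 detections is a false positive —
the listening-evoked cortical activity engages it — while the perceptually
trained detector stays silent. The verification gate (`fit_verifier()`,
`verify()` at threshold 0.65) adds a second layer of specificity on top;
`tests/testthat/test-acceptance.R` runs the full 10-seed system-level
comparison.

Offline analyses use the same session objects:

```r
s <- simulate_session(sim_config(
  n_electrodes = 32,
  schedule = list(type = "isolated_target",
                  task = c("speech", "reading", "listening"), n_trials = 201),
  seed = 11))
maps <- lapply(c(speech = "speech", reading = "reading",
                 listening = "listening"),
               function(tk) responsiveness(s, tk))
shared_set(maps)$shared
#> [1] 1 2 3 4 5
```

which exactly recovers the five designed shared electrodes.

## Command line

```sh
Rscript -e 'ecodec::ecodec_cli()' simulate --config sim.json --seed 7 --out session.rds
Rscript -e 'ecodec::ecodec_cli()' detect train --session session.rds --out model.rds
Rscript -e 'ecodec::ecodec_cli()' detect run --session session.rds --model model.rds --out events.json
Rscript -e 'ecodec::ecodec_cli()' evaluate --session session.rds --events events.json --report report.json
```

(An executable wrapper is installed at `inst/cli/ecodec`.)

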