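---
title: "Decoding attempted speech from sensorimotor ECoG: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attempted speech from sensorimotor ECoG: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A speech neuroprosthesis records cortical field potentials from an
electrocorticography (ECoG) array over sensorimotor cortex while a person with
anarthria attempts to speak, and decodes those attempts into words. The
sensorimotor cortex, however, is not silent during perception: reading and
listening activate overlapping neural populations, so a naively trained
decoder can fire when the user is merely reading an article or listening to a
podcast. `ecodec` implements a decoding stack built around *specificity to
volitional speech*:

1. **Features.** Two normalized feature streams per electrode at 200 Hz: the
   high-gamma amplitude (HGA; envelope of the 70–150 Hz band, a proxy for
   local population firing) and the low-frequency signal (LFS; 1–100 Hz),
   each normalized by a causal 30 s sliding z-score.
2. **Detection.** A strictly causal 3-layer LSTM emits probabilities over
   five classes — silence, speech preparation, speech, reading, listening —
   at 200 Hz. A causal moving average, a probability threshold
   $\theta_p$, and time thresholds $T_{on}, T_{off}$ (default 100 samples =
   0.5 s) convert the speech probability into discrete events with onset
   $d^*$. Perceptual classes are part of the *training* objective only; only
   the speech probability drives event extraction.
3. **Verification.** A 4 s window around $d^*$ (default $[-1, 3]$ s,
   downsampled to 33.3 Hz) is classified as attempted speech / reading /
   listening (optionally non-speech movement) by an ensemble of
   conv + 2-GRU networks; the event is accepted only if the ensemble-mean
   speech probability strictly exceeds $\theta_v = 0.65$.
4. **Classification.** Accepted windows are mapped to a 10-word vocabulary by
   a second conv + GRU ensemble (softmax over the vocabulary; ties broken
   toward the lowest index).
5. **Evaluation & mapping.** Detection-to-attempt matching within 0.5 s with
   duplicate detections counted once; TPR/FPR; pseudo-blocks (visualization
   only); 10-fold stratified cross-validation with per-fold ensembles and
   validation-based early stopping; Fisher exact, rank-sum, Holm–Bonferroni
   and permutation-correlation statistics; per-electrode responsiveness maps,
   shared-electrode sets, gradient-based contribution maps, multitaper
   theta/beta power contrasts, and longform-activation tests.

Because the clinical recordings behind the original study are
access-restricted, the package ships a first-class **simulator** whose output
feeds every stage, with ground truth for every quantity the analyses try to
recover.

## The simulator's stated world

`sim_config()` fixes the generator's world. Values with an asterisk come
directly from the findings the generator is meant to emulate; the rest are
desk-scale choices made once and kept.

| Parameter | Default | Why |
|---|---|---|
| shared-electrode gains (speech/read/listen) | 3 / 2 / 1 z* | evoked-HGA ordering at shared electrodes |
| pre-cue ramp (shared, speech trials) | 1 z* | pre-go-cue activation of shared electrodes |
| word-tuning multipliers | log-normal, log-sd 0.25* | weak single-electrode word selectivity |
| tuning phase | shared: pre-cue; articulatory: post-cue* | motor-planning vs articulation |
| HGA noise | AR(1), $\rho$ = 0.95, sd 1* | autocorrelated high-gamma background |
| evoked kernel | gamma density (shape 2, scale 0.25 s), peak-normalized | smooth ~1 s unimodal bump |
| theta/beta modulation | −0.5 during speech; +0.3 during perception* | movement-related desynchronization vs perceptual synchronization |
| oscillations | 8 Hz and 25 Hz, amplitude 0.6 on AR(1) background | inside the 5–12 / 20–30 Hz analysis bands |
| electrode classes | shared .15, articulatory .20, auditory .15, visual .10, silent .40 | qualitative grid composition |
| timing | 2 s countdown, 0.2 s attempt latency, 1.5 s attempts, 2 s stimuli, 2 s ITI + 0-0.5 s jitter | compressed but realistic trial design; the jitter keeps trial onsets off any exact lattice shared by the oscillation periods and the 6-sample downsampling grid, which would otherwise leak sampling phase as a spurious class cue |
| self-paced online delays | uniform 2–8 s | desk-scale stand-in for the tens-of-seconds reading delays |
| `snr` | 1 | global multiplier on all evoked gains |

Auditory (temporal-lobe) electrodes respond to listening (gain 3) and, more
weakly, to attempted speech (gain 1.5), with *task-specific* word codes by
default (`word_code_sharing = "independent"`); this encodes the study's
finding that listening and attempted speech do not share a word
representation, and provides the negative/positive controls for the
cross-task-transfer analysis.

What the generator does **not** emulate: biophysical field-potential physics,
volume conduction, line noise, eye-movement artifacts, stimulus-volume
effects, or non-stationarity across days. A green test therefore establishes
that the *algorithms* recover designed structure at realistic SNR — not that
they would meet clinical performance numbers.

Two fixture conventions are used in tests: recovery analyses that depend only
on mean evoked responses (responsiveness, shared sets, band power) run at the
stated-world `snr = 1`; classifier-based checks use the "high-SNR" fixture
`snr = 2`, because single-trial 10-way word decoding from a 16-electrode grid
at `snr = 1` carries only ~25% recoverable accuracy (verified against a
nearest-class-mean oracle), which is too close to chance to test orderings.

## Numerical and design choices

* **Filters.** Band extraction uses linear-phase windowed-sinc FIR filters
  (Hamming), applied zero-phase by exact group-delay compensation offline, or
  causally for streaming. The envelope is the analytic-signal magnitude. An
  IIR design would add nothing at desk scale and is harder to make exactly
  zero-phase.
* **Sliding z-score warm-up** uses growing-window statistics over the first
  30 s; the running standard deviation is floored at $10^{-6}$ so constant
  channels normalize to 0.
* **Artifact screen.** The aggregate metric is the 30th percentile across
  electrodes of a 15 s ($[-5, +10]$ s) rolling HGA standard deviation; trials
  are flagged after the metric stays below 0.6 for a sustained run (default
  1 s). Note that because the rolling window is 15 s long, only suppressions
  covering most of that window can pull the metric below 0.6 — brief dips are
  invisible by construction.
* **Networks.** No deep-learning framework is assumed: the LSTM, GRU and
  temporal-convolution layers (and their backward passes, verified against
  finite differences) are implemented in C++/Armadillo. All randomness flows
  through R's RNG, so training is bit-reproducible on CPU. The GRU update
  gate is initialized with bias +2 so that early-window evidence survives to
  the final-state readout; without it the final-state classifier is dominated
  by the post-bump tail of the window. Training uses Adam with optional
  decoupled weight decay; cross-validation reserves 10% of each training
  split for early stopping (patience 5).
* **Detector ablations** keep the 5-way output head but *mask excluded-class
  samples out of the loss* rather than relabeling them as silence: the
  ablated model must never see perceptual data, otherwise it would be
  explicitly taught to suppress the very false positives the ablation is
  meant to expose.
* **Event extraction** records the onset at the threshold-crossing sample
  (recognized $T_{on}/200$ s later) and the offset at the last supra-threshold
  sample (recognized after $T_{off}$ sub-threshold samples). Gaps shorter
  than $T_{off}$ merge. Because of merging, raising $\theta_p$ can in
  principle split one event into two, so the monotonicity property
  ("higher threshold, no more events") is asserted on unimodal per-attempt
  probability bumps — the regime a trained detector actually produces — not
  on adversarial traces.
* **Verification threshold** is strict (`> 0.65`); ensembling averages member
  probabilities; the context-length analysis picks its operating threshold by
  minimizing FP + FN on a validation split.
* **Matching** is onset-to-onset with 0.5 s tolerance; a detection within
  tolerance of two attempts goes to the nearer (ties: earlier) attempt;
  duplicate detections of one attempt count once in both TPR and FPR.
* **Multitaper power** uses DPSS tapers (time–bandwidth 3, 5 tapers) computed
  from the standard tridiagonal eigenproblem; band power is the
  two-sided-corrected in-band sum, normalized so a sinusoid of amplitude $a$
  yields $a^2/2$.
* **Statistics.** The rank-sum Z uses the tie-corrected normal approximation;
  Holm correction fans out over exactly the comparisons performed;
  correlation p-values use add-one-corrected permutation counts.
* **Responsiveness calibration.** The per-trial z-score baseline
  ($[-2,-1]$ s before presentation) is kept disjoint from the pre-stimulus
  comparison window ($[-1,0]$ s): if the two coincide, the pre-trial group is
  pinned near zero by construction and the rank-sum test is anti-conservative
  (measured familywise type-I of ~8.5% at $\alpha = 0.05$); with disjoint
  windows the null calibration is clean.
* **Session container.** The environment provides no R HDF5 binding, so the
  session container is a single RDS file with the same logical schema
  (`hga`, `lfs`, `labels`, `trials`, `events`, `electrodes`); round-trips are
  bit-exact. CLI configs are JSON.

## Known limitations

* Input-gradient (saliency) contribution maps computed from these small
  from-scratch networks concentrate only weakly on the designed-informative
  electrodes (~0.46–0.5 of total mass against a 0.44 uninformative baseline
  in the default fixture, at 80%+ decoding accuracy). The first network layer
  remains close to its random initialization, so sensitivity spreads across
  input channels even when the decision function relies on the informative
  ones. The corresponding acceptance check (≥ 70% mass) is implemented
  faithfully and left failing rather than weakened; the directionally-true
  property (informative electrodes contribute more than silent ones, masked
  channels contribute exactly zero, rankings stable under perturbation) is
  asserted in the unit tests.
* Desk-scale networks and trial counts put absolute accuracies well below the
  published clinical figures; all clinical-scale numbers are treated as
  qualitative orderings only.
* The exhaustive event-extractor equivalence is run for all binary traces up
  to length 12 plus large random samples of longer traces; full enumeration
  to length 20 (≈ 2M traces) is outside the test-time budget.
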