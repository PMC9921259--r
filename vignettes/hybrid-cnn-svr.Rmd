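---
title: "Cuff-less blood pressure estimation with a hybrid CNN-SVR model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuff-less blood pressure estimation with a hybrid CNN-SVR model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Arterial blood pressure varies beat by beat, but the cuff devices used to
measure it are intermittent and occlusive. A long line of work therefore
tries to estimate systolic and diastolic pressure (SBP, DBP, in mmHg)
continuously from signals that are easy to wear: the electrocardiogram
(ECG) and the fingertip photoplethysmogram (PPG). The physiological anchor
is pulse transit time (PTT) — the interval between the ECG R-wave and the
arrival of the corresponding pulse at the periphery — which shortens as
pressure rises, because stiffer, more pressurized arteries conduct the
pulse wave faster.

`cuffbp` implements a hybrid estimator that never computes PTT or any other
engineered feature explicitly. Instead, a small one-dimensional
convolutional network (CNN) is trained on raw one-second ECG/PPG beat
windows to predict (SBP, DBP); its penultimate activations are then used as
a learned feature vector for a pair of epsilon-insensitive support vector
regression (SVR) models with a radial basis function (RBF) kernel, one per
pressure target. The CNN supplies representation learning; the SVR supplies
a robust, margin-based regressor on top of it.

## Pipeline

1. **Ingestion.** Records are multichannel waveforms at 125 Hz with an ECG
   lead (AVR preferred, then II, I, III, V), a `PLETH` channel and per-beat
   `ABP Sys` / `ABP Dias` reference labels, read from labelled CSV matrices
   or WFDB format-16 files. The collection protocol skips the first minute
   of a recording and keeps seven one-minute windows separated by 30-s gaps,
   i.e. seven minutes of signal per subject from eleven minutes of source.
2. **Preprocessing.** ECG baseline wander (respiratory, roughly 0.15-0.2 Hz)
   is removed by least-squares polynomial detrending; both channels are then
   denoised with a Savitzky-Golay filter and min-max normalized per record.
3. **Beat segmentation.** R-peaks are detected on the normalized ECG by
   thresholding local maxima above 0.5 with a minimum peak distance of 125
   samples (one cardiac cycle at 60 bpm); conflicts keep the taller peak.
   Each beat is an R-centered 125-sample window per channel: the
   RR-midpoint-bounded cycle is symmetrically truncated (below 60 bpm) or
   zero-padded (above 60 bpm), with the R-peak at the central sample
   (position 63). Each beat takes the BP label nearest its R time (ties to
   the earlier label; beats with no label within 30 s are dropped).
4. **CNN.** Five blocks of [convolution -> batch normalization -> ReLU ->
   average pooling], a 20% dropout layer, and a two-unit linear head trained
   with the half-mean-squared-error loss by mini-batch SGD.
5. **SVR.** The flattened block-5 activations are standardized and fed to
   one RBF-kernel epsilon-SVR per target, with C, gamma and epsilon chosen
   by grid search under subject-grouped 10-fold cross-validation.
6. **Evaluation.** Accuracy within a tolerance, RMSE, MAE, error SD and mean
   error per target, plus an AAMI SP10 compliance report (MAE <= 5 mmHg,
   error SD <= 8 mmHg, cohort >= 85 subjects).

Subjects are split 70/30 into training and test sets before any model
fitting; splitting by beat is rejected at configuration time because it
leaks test subjects into training.

## The synthetic cohort generator

Clinical waveform databases with beat-aligned arterial pressure labels are
restricted-access, so the package ships a simulator that reproduces the
statistical structure the estimator relies on:

* **ECG**: each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with
  fixed relative timings and widths scaled by the RR interval. The R bump
  dominates, so after min-max normalization the 0.5 threshold detector is
  well posed (the T-wave normalizes to about 0.43).
* **PPG**: one gamma-shaped pulse per beat whose first support sample sits
  exactly `round(ptt * fs)` samples after the R-peak; PTT varies per beat as
  `ptt_base + N(0, ptt_sd)`, truncated at 0.05 s.
* **Labels**: `BP_i = a + b / ptt_i + noise`, calibrated per subject so the
  baseline PTT maps to the subject's baseline pressures. With zero noise the
  per-beat Spearman correlation between PTT and SBP is exactly -1.
* **Noise**: additive Gaussian noise on both waveforms plus a sinusoidal
  ECG baseline drift with frequency drawn from 0.15-0.2 Hz, exercising the
  detrending stage.

Two modelling choices deserve emphasis:

* **Cohort-level coupling.** Subject baseline pressures are not drawn
  independently: they follow a cohort-wide inverse law (`SBP = 30 / PTT`,
  `DBP = 15 / PTT`, mmHg with PTT in seconds) plus a small subject offset
  (SD 2 / 1.5 mmHg). In a calibration-free setting the estimator sees a new
  test subject with no per-subject baseline information, so if baselines
  were independent of the waveforms no estimator could recover them. The
  global law keeps between-subject differences physiologically coupled to
  the waveform timing, which is exactly the premise of PTT-based estimation.
* **What the simulator does not model.** No Windkessel or PDE hemodynamics,
  no arrhythmia or ectopy, no motion artifacts, no PPG morphology changes
  with vascular tone. Passing tests on synthetic cohorts therefore shows
  that the pipeline recovers the structure it assumes; it does not certify
  performance on ICU data, where waveform quality and BP dynamics are far
  richer.

Default generator conditions (fixed once, used by every test and by
`scripts/acceptance.R`): 125 Hz, heart rate 60 bpm cohorts with 2% RR
jitter, `ptt_base` uniform on 0.20-0.32 s, `ptt_sd` 0.015 s, waveform noise
SD 2% of the R amplitude, BP label noise SD 1 mmHg, drift amplitude 0.2 mV.
At 60 bpm the per-beat SBP swing implied by `ptt_sd` is roughly 7 mmHg,
comparable to real beat-to-beat variability.

Because PPG pulses are placed at integer samples, PTT is observable only to
8-ms resolution; at the cohort's coupling slope (about 480 mmHg/s at
PTT = 0.25 s) one sample corresponds to roughly 3.8 mmHg of SBP, which sets
a floor on the achievable per-beat error. An RR interval of exactly one
second also sits exactly at the 125-sample minimum peak distance, so any
beat-to-beat jitter makes the detector drop a fraction of beats (by design:
the suppression rule is part of the method); zero-jitter records keep every
beat, which is what the exact-count protocol checks use.

## Numerical and design choices

* **Detrending window.** A degree-d polynomial over T seconds can only
  follow oscillations up to about d/(2T) Hz. A degree-6 fit over a full
  minute (0.05 Hz) cannot track 0.15-0.2 Hz wander — measured removal is
  about 3% of band power — so the pipeline applies degree 6 per 10-s window,
  which removes over 99% of the band while distorting a clean ECG by only
  about 0.01 mV RMS. Both the degree and the window are configurable.
* **Savitzky-Golay defaults.** Window 15 samples (120 ms), order 3:
  preserves QRS-scale structure (80-120 ms) while smoothing high-frequency
  noise. Edges are mirror-padded by half a window, so output length equals
  input length and interior samples reproduce polynomials of degree <= 3
  exactly. The PPG is smoothed and normalized but not detrended.
* **Threshold semantics.** The 0.5 detection threshold applies to the
  min-max-normalized ECG (signals are normalized before detection), not to
  raw millivolts; both the threshold and the minimum distance are
  configurable in `peak_config()`.
* **CNN architecture.** Channel widths (16, 32, 64, 128, 256), kernel
  length 5, pooling width 2. The temporal length contracts
  125 -> 62 -> 31 -> 15 -> 7 -> 3, giving a 768-dimensional feature vector.
  The published description fixes five blocks, batch normalization, ReLU,
  average pooling, 20% dropout and the two-unit head, but not the per-block
  widths; geometric widening is the standard choice at this scale. The
  feature tap is the flattened block-5 output: the two-unit head is too
  low-dimensional to act as a feature vector.
* **Learning-rate schedule.** The training protocol is SGD (momentum 0.9),
  initial rate 0.001, mini-batch 60, with a piecewise drop of 0.1. Read
  literally as "multiply by 0.1 every epoch" the rate reaches 1e-31 by
  epoch 30 and training freezes after a handful of epochs; the default
  therefore drops once per 10 epochs (`lr_step = 10`), and the literal
  per-epoch reading is available as `lr_step = 1`. The output bias is
  initialized at the training-target means so the head does not have to
  climb from 0 mmHg at a 0.001 learning rate.
* **Targets** are regressed in raw mmHg, keeping the half-MSE loss in
  interpretable units.
* **SVR gamma scale.** The tuning grid uses C in {10, 100}, gamma in
  {10, 100} and epsilon in {0.01, 0.1, 1} (a three-point discretization of
  the stated 0.01-1 range). On standardized 768-dimensional activations the
  mean squared pairwise distance is on the order of 1,500, so an absolute
  gamma of 10 collapses the kernel matrix to the identity and the model
  degenerates to its bias. Grid gammas are therefore interpreted relative to
  the data scale: the effective kernel parameter is gamma divided by the
  mean squared pairwise distance of the standardized training features
  (estimated on a seeded subsample). This keeps the published grid
  meaningful for any feature dimensionality; `gamma_scale = "none"` gives
  absolute semantics, and all kernel- and solver-level tests use it.
* **SVR problem size.** The SVR stage fits on up to 80 beats per training
  subject (the CNN trains on all beats): the kernel matrix and the solver
  cost grow quadratically in the beat count, and the ~300-420 beats of a
  seven-minute record are highly redundant for a per-subject pressure
  level. The cap is configurable (`svr_beats_per_subject`). Grid points are
  scored in cross-validation with a looser solver tolerance (`cv_tol`,
  default 1e-2 on the KKT gap in mmHg) than the returned refit (`tol`,
  1e-4): fold fits only rank candidates, and the ranking is insensitive to
  the last decades of dual convergence.
* **Solver.** The epsilon-SVR dual is solved by a compiled SMO-style
  maximal-violating-pair method over a precomputed kernel matrix
  (`src/svr_smo.cpp`), which lets the 12-point grid under 10-fold
  cross-validation reuse one distance matrix per fold. Tests verify the
  solution against a dense interior-point quadratic program and an
  independent SMO implementation; KKT box and balance constraints are
  asserted after every fit. Cross-validation folds are grouped by subject
  so no subject straddles a fold boundary.
* **Accuracy tolerance.** "Correct estimation" for the accuracy percentage
  is not standardized; the default counts estimates within 5 mmHg
  (AAMI-aligned) and the tolerance is exposed in the report.
* **Determinism.** A single global seed fans out to named substreams
  (simulator, split, CNN initialization, shuffling, dropout, CV folds,
  subsampling). Two runs with the same configuration and seed produce
  bit-identical metrics in single-threaded BLAS mode; multi-threaded BLAS
  may reorder floating-point reductions.

## Problem sizes used in the package's own evaluation

The reference synthetic study (`synthetic_study_config()`) uses 40 subjects
at seven minutes each (about 11,600 detected beats), a subject-disjoint
70/30 split, 10 CNN epochs and the full SVR grid under 10-fold
cross-validation. On this cohort the pipeline's pooled test-split MAE and
error SD for both targets fall inside the AAMI SP10 error bounds, which is
what `scripts/acceptance.R` and the acceptance tests recompute end to end.
The exact-count protocol checks run 120 zero-noise subjects through the
full eleven-minute collection protocol. Cohort size, epochs and durations
are all configurable upward; the defaults keep a complete run in the
single-digit minutes on one CPU core.

## Known limitations

* Calibration-free estimation interpolates across subjects: a held-out
  subject whose baseline pressure lies outside the span of the training
  cohort gets predictions shrunk toward the training mean (kernel
  regressors do not extrapolate). With ~10 subjects a single uncovered
  test subject can dominate the pooled error; from a few tens of subjects
  onward the baseline-PTT range is covered densely and the effect
  disappears.
* The simulator's PTT-to-BP law is stationary within a record; real
  pressure drifts (vasomotion, medication, posture) are not modelled, so
  the within-subject dynamic range is narrower than in ICU data.
* Integer-sample pulse placement bounds the achievable SBP resolution (see
  above); a sub-sample onset model would remove this floor but would no
  longer match the sampling process of 125-Hz databases.
* The minimum-peak-distance rule discards beats whenever the instantaneous
  rate exceeds 60 bpm; labels remain correctly aligned, but per-subject
  beat counts then fall below the nominal rate x duration.
* Batch normalization uses running statistics frozen at inference; features
  for a beat are therefore independent of its batch, but a model trained on
  one cohort scale should be re-trained rather than fine-tuned for records
  with very different amplitude statistics.
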