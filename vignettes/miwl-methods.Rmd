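---
title: "Workload estimation by mutual-information fusion of EEG and vehicular signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Workload estimation by mutual-information fusion of EEG and vehicular signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Electroencephalography (EEG) is among the most sensitive objective measures
of a driver's mental workload (MWL), but recording EEG in a moving car is
impractical for everyday monitoring. Vehicular telemetry — velocity,
acceleration, lateral and longitudinal acceleration — is available in any
modern vehicle at no cost to the driver. `miwl` implements a fusion
methodology that uses EEG once, during a calibration drive, to learn how
much information each vehicular channel shares with the EEG workload
signature, and afterwards evaluates workload from vehicular data alone.

The package has three layers:

1. an **EEG spectral pipeline** producing a per-epoch workload index,
2. a **mutual-information (MI) template** linking vehicular features to EEG
   band-power features, with a projection that produces "MI-based" features
   from vehicular data only, and
3. an **evaluation harness** (model zoo, cross-validation schemes, metrics,
   and paired statistical tests).

Because the driving data the methodology was developed on are not publicly
deposited, the package ships a first-class **session simulator** with a
known latent workload trace, which makes parameter-recovery claims
testable.

# EEG processing and the workload index

The expected montage is 15 channels (Fpz, Fz, Pz, POz, Oz, AF3, AF4, F3,
F4, P3, P4, P5, P6, O1, O2) at 256 Hz. The chain is:

* **Band-pass filtering** (`bandpass_filter()`): fourth-order Butterworth,
  1–30 Hz, applied forward–backward. The zero-phase application is a
  deliberate choice for this offline chain: it prevents phase distortion
  from leaking band power across the epoch boundary.
* **Blink correction** (`remove_blinks()`): blink intervals are detected on
  the low-pass-filtered Fpz reference by an amplitude criterion (default
  40 µV, 4 Hz low-pass, 100 ms padding); within the intervals the
  least-squares projection of each channel on the reference is subtracted.
  Outside the intervals the data are untouched and no samples are dropped.
  This regression-on-reference design exploits the fact that blink
  artifacts share a fixed frontal topography.
* **Epoching** (`segment_epochs()`): 2 s windows shifted by 0.125 s
  (0.875 s overlap between contiguous epochs gives 1.875 s overlap across
  the 2 s span, i.e. 16× oversampling of the epoch grid); the count is
  `floor((T − 2)/0.125) + 1`. Epoch k covers the half-open interval
  `[k·0.125, k·0.125 + 2)` s.
* **Artifact rejection** (`reject_artifacts()`): an epoch is dropped when
  any channel (i) exceeds ±100 µV, (ii) has an ordinary-least-squares trend
  steeper than 10 µV/s, or (iii) contains a sample-to-sample step above
  25 µV. The trend criterion is implemented as the OLS line over the whole
  epoch — the standard reading of a "slope after interpolation" rule. All
  three criteria are evaluated after filtering and blink removal, as the
  final cleaning stage.
* **PSD** (`compute_psd()`): Hann-windowed periodogram per epoch and
  channel, 0.5 Hz resolution, calibrated so that `sum(psd)·Δf` equals the
  window-normalized signal power (a Parseval identity the tests assert).
* **IAF** (`estimate_iaf()`): the individual alpha frequency is the peak of
  the epoch- and channel-averaged PSD over posterior channels in 8–12 Hz,
  computed from a one-minute closed-eyes resting recording. Ties are an
  error rather than an arbitrary choice. Bands are anchored at the IAF:
  theta `[IAF−6, IAF−2]`, alpha `[IAF−2, IAF+2]`, beta `[IAF+2, IAF+18]`.

Two feature matrices come out of the PSD:

* `band_features_45()`: mean band power per rhythm and channel
  (3 × 15 = 45 columns, canonical order `theta, alpha, beta` within each
  channel).
* `roi_psd_matrix_187()`: raw PSD bins over the workload regions of
  interest — 11 channels (5 frontal, 6 parietal) × 17 bins from IAF−6 to
  IAF+2 Hz. Only 99 columns are *eligible* for the workload discriminant:
  frontal channels in the 9 theta bins (45) and parietal channels in the 9
  alpha bins (54). The frontal set excludes Fpz because that channel is
  consumed as the blink reference; 5 frontal channels is also the only
  assignment consistent with 45 = 5 × 9 eligible frontal features out of
  11 ROI channels. Band-edge bins are inclusive on both sides, which is
  what makes 17 = 8 Hz/0.5 Hz + 1 bins and 9 bins per sub-band; the IAF−2
  edge bin is eligible on both channel groups.

The **workload index** (`train_asswlda()`) is a stepwise linear
discriminant in the classical SWLDA formulation: 0/1 labels (Easy = 0,
Hard = 1) regressed on eligible ROI columns with forward selection
(partial-F p ≤ 0.05), backward elimination (p ≥ 0.10), and an automatic
stop when no candidate qualifies or the BIC would not improve. The original
automatic-stopping rule of this algorithm family is patented and not
disclosed; the BIC guard is this package's documented stand-in, and all
three constants are exposed as arguments. Least-squares weights on the
selected columns make the discriminant `y(t) = Σ w_i f_i(t) + b` come out
near 0 on easy epochs and near 1 on hard ones; the output is deliberately
not clipped, since values outside [0, 1] carry information. The final
index, MWL score, is a trailing (causal) 8 s moving average of `y(t)` — 64
epochs at the 0.125 s shift, with an expanding window during the first 8 s.
A causal window keeps the index usable online; its price is a group delay
of about half the window, which matters when comparing the index to a
ground-truth trace (see *Recovery studies* below).

# Mutual-information template and projection

Entropy, conditional entropy and MI (`estimate_entropy()`,
`estimate_conditional_entropy()`, `estimate_mutual_information()`) are
reported in bits. Two estimators are provided:

* **histogram** (default): plug-in estimates over equal-width bins
  (16 per axis by default, over the sample range or a supplied support).
  The plug-in identities hold exactly: MI is symmetric and non-negative,
  `H(Y|X) ≤ H(Y)`, and on discrete data the estimate equals the direct
  double sum over the joint frequency table.
* **knn**: Kozachenko–Leonenko entropy and the
  Kraskov–Stögbauer–Grassberger MI estimator (k = 3, max-norm), implemented
  in C++. Small negative MI estimates are clamped to zero and flagged. The
  KSG estimator is the one to use for continuous data when absolute
  calibration matters: at n = 50 000 it reproduces the Gaussian closed form
  within a few hundredths of a bit, whereas a 16-bin histogram
  underestimates strong dependence by ≈ 0.1 bit.

`build_template()` computes the p × q matrix of pairwise MI between each
vehicular feature (p = 4) and each EEG band feature (q = 45), both min–max
scaled to [0, 1] on row-aligned kept epochs, and summarizes each row by its
norm (Euclidean by default, L1 by option). `project_features()` then maps a
new scaled vehicular row `v'` to MI-based features `m' = v' ∘ ‖I(E,V)‖` —
an **elementwise** product. The template equation can also be read as a
scalar dot product, but the downstream feature count is fixed at four (one
per vehicular channel), which is only consistent with the elementwise
reading; the dot-product variant is available behind `mode = "dot"` for
comparison. Templates are estimated on training rows only: the template is
the deployable artifact and must not see test data.

**Finite-sample bias floors.** Plug-in MI is positive under independence.
With the 16× overlapping epoch grid and signals whose autocorrelation
spans seconds, the effective sample size is far below the row count and
the floor rises well above the i.i.d. value. `mi_bias_floor()` measures
the floor empirically with circular-shift surrogates (rotating one series
by large offsets preserves both marginals and both autocorrelation
structures while destroying the pairing); "≈ 0" assertions in the tests are
made relative to that floor, not to zero.

# Vehicular processing

Telemetry arrives at 10 Hz (velocity km/h, acceleration, lateral and
longitudinal acceleration m/s²). `resample_to_eeg_rate()` performs the
10 → 256 Hz rational resampling as a zero-phase polyphase interpolator: a
symmetric Kaiser-windowed sinc kernel (cut-off 4.8 Hz, just under the
input Nyquist; half-width 1 s, i.e. 513 taps on the output grid; β = 6)
evaluated at the exact fractional offset of every output sample, with
per-sample weight renormalization. The renormalization preserves constants
exactly and keeps content below ≈ 4 Hz within 1 % RMS; edges are handled by
replication. This is algebraically the up-sample/low-pass/down-sample
cascade without materializing a 2560 Hz intermediate.

`epoch_align()` reduces the 256 Hz signal to one row per kept EEG epoch by
the arithmetic mean over the 512-sample window — a variance-reducing,
phase-free choice for a reduction the method leaves unspecified.
`minmax_normalize()` learns column ranges on the training split and freezes
them; applying frozen ranges clips to [0, 1]. Global normalization (fit on
everything) leaks test information into training, so train-only ranges are
the default; passing explicit ranges reproduces the global behaviour when
wanted.

# Evaluation harness

`model_spec()`/`build_model()` cover the five reference model families with
their fixed hyperparameters: linear regression; ridge-penalized logistic
regression with balanced class weights (glmnet, λ = 1/n matching a unit
inverse-regularization constant); a multilayer perceptron with hidden
layers 32/16/4, ReLU, Adam, batch 128, up to 500 epochs with a 1e-4
improvement tolerance (no installed R package provides a multi-hidden-layer
perceptron, so the package implements this one directly in R matrix
algebra); a random forest of 100 bootstrapped depth-5 trees (ranger); and
an RBF SVM with degree 3, C = 1, ε = 0.2 (e1071). Classification scores are
positive-class probabilities (decision values for the SVM).

`split_scheme()` provides 10-fold CV, leave-one-subject-out CV, and a
stratified 10 % holdout; `run_experiment()` runs a model zoo under a scheme
deterministically for a given seed and reports per-fold metrics plus
min/max/mean summaries. `classification_metrics()` reports sensitivity,
specificity, precision, recall, F1, accuracy and balanced accuracy, with
zero-denominator ratios returned as `NA` (undefined), never silently 0.

Statistical comparisons: `wilcoxon_signed_rank()` enumerates the exact
null of the positive-rank sum for n ≤ 12 (midranks for ties; the reported
statistic is min(W+, W−) two-sided and W+ one-sided) and uses a
tie-corrected normal approximation with continuity correction otherwise.
`delong_auc_test()` compares two correlated AUCs through placement-value
covariances, with one-sided default (first AUC greater) and 95 % CIs per
AUC. `roc_auc()` is the normalized Mann–Whitney statistic with half-credit
ties.

# The session simulator

`sim_config()`/`make_session()` generate coupled EEG + vehicular sessions
with ground truth. The design targets the *statistical structure the
method assumes*, not biophysical realism:

* **Latent workload trace** (256 Hz, in [0, 1]): a scheduled baseline —
  Easy 0.42, Hard 0.51, +0.05 during Rush hour, +0.10 while an event (Car
  or Pedestrian) is active; the segment levels are the group means reported
  for real urban drives — plus AR(1) noise with coefficient 0.999 at
  256 Hz (≈ 4 s correlation time; workload varies slowly relative to the
  0.125 s epoch shift) and stationary sd 0.15 (chosen once as a plausible
  within-session fluctuation, roughly half the between-condition spread of
  real group data), clipped to [0, 1].
* **EEG**: per channel, 1/f background (10 µV sd, scalable), a theta
  oscillation at IAF−4 Hz whose frontal amplitude grows affinely with the
  trace, an alpha oscillation at IAF whose posterior amplitude shrinks
  affinely with the trace (gains 6 µV per unit workload), blink transients
  (400 ms raised cosine, 80 µV at Fpz, fixed decaying topography — exactly
  the structure a regression-on-reference correction exploits), and sparse
  0.5 s high-amplitude bursts that trip the artifact criteria. A
  closed-eyes mode triples posterior alpha for IAF estimation.
* **Vehicular** (10 Hz): velocity = segment baseline (Easy 44.69, Hard
  37.81 km/h) − coupling · 30 km/h · (trace − scheduled segment/hour
  baseline) + smoothed noise (sd 3 km/h); acceleration is its first
  difference; lateral/longitudinal accelerations are coupling-weighted
  smoothed transforms of the same excursion plus noise. The **coupling**
  parameter in [0, 1] is the single knob tying vehicular behaviour to the
  latent trace: at 0 the vehicular channels are statistically independent
  of the trace. Events enter the *trace* only, so they reach vehicular
  signals exactly through the coupling — which is the property the fusion
  method needs to exploit.

What the simulator does **not** emulate: volume conduction and realistic
scalp topographies, non-stationary alpha dynamics, eye movements other
than blinks, road geometry (curves, stops), or between-subject
variability beyond the IAF and gain parameters. Passing recovery tests on
simulated sessions therefore demonstrates that the pipeline recovers the
structure it assumes, not that the assumptions hold for any particular
real recording.

# Recovery studies and numerical choices

The test-suite and the acceptance script run the following studies (sizes
chosen to keep each study in the seconds-to-minutes range):

* **Workload-index recovery**: a two-class session (2 laps × 60 s Easy +
  60 s Hard, ≈ 1 900 epochs) is processed end to end; the discriminant is
  trained on Easy/Hard labels and its smoothed score is correlated with
  the latent trace. Because the score is a *trailing* 8 s average, it is
  compared with the trace averaged by the same trailing window — same
  temporal support on both sides; against the instantaneous trace the
  causal lag alone costs ≈ 0.2 in correlation. Pearson r ≥ 0.7 is the
  pass mark.
* **Planted-feature recovery**: 20 seeded runs of 2 000 × 187 Gaussian
  matrices with three eligible columns shifted by d = 1.5 between classes;
  the stepwise selector must recover all three in ≥ 90 % of runs, and on
  pure noise it must stop with ≤ 3 columns and chance-level training AUC.
* **Coupling sweep**: long Easy-only sessions (840 s, 20 events) at
  coupling 0, 0.5, 1. EEG-vehicular templates are built, vehicular
  features projected, and a random forest classifies event vs. non-event
  epochs. Two protocol details matter: (i) the train/test split is
  *temporally blocked* (contiguous blocks, alternately assigned), because
  with 16× overlapping epochs a random split leaks near-duplicate rows and
  inflates AUC even at coupling 0; (ii) the statistical unit is the event
  instance (≈ 20 per session), not the epoch, so the AUC is averaged over
  three replicate sessions with paired seeds. Expected behaviour: AUC
  ≈ 0.5 at coupling 0 and monotone growth with coupling. The per-session
  Bayes limit is modest by construction — event-driven excursions share
  the channel, the timescale and the magnitude of ordinary workload
  fluctuations — so mid-0.6 AUCs at full coupling are the honest ceiling
  under these conditions, not a pipeline defect.
* **Estimator calibration**: KSG MI at n = 50 000 against the Gaussian
  closed form (ρ = 0.9 → 1.198 bits, tolerance ±0.1); KL entropy against
  the Gaussian closed form; histogram MI against exact joint-table
  evaluation (tolerance 1e−12); median KSG error monotone decreasing over
  n ∈ {10³, 10⁴, 5·10⁴}.
* **Statistics**: exact Wilcoxon p equals full 2ⁿ enumeration for n ≤ 12;
  AUC equals brute-force pair counting; DeLong against pROC (independent
  implementation) and against a 2 000-resample paired bootstrap within
  0.02; DeLong CI coverage ≈ 95 % over 200 calibrated replicates.

Degenerate inputs are errors, not silent defaults: constant columns
without supplied scaling ranges, tied alpha peaks, single-class training
labels, all-zero Wilcoxon differences, epoch grids extending beyond the
signal.

# Known limitations

* The stepwise stopping rule is a documented stand-in for an undisclosed
  patented rule; selected feature sets will differ from the original
  implementation even on identical data.
* The published group-level results on the original driving data
  (mean absolute errors, real-data AUCs, nine-driver signed-rank p-values)
  are data-dependent and cannot be reproduced without that data; the
  package reproduces every *derivable* quantity (all confusion-table
  metrics) and substitutes property-based recovery studies for the rest.
  Two cells of the published holdout tables are arithmetically
  inconsistent with their own printed confusion counts (a specificity of
  647/793 printed as 0.81, an F1 of 684/1397 printed as 0.50); the
  package asserts the recomputed values.
* Histogram MI values depend on the binning; reported template magnitudes
  are estimator-specific (the estimator and its parameters travel with the
  template in `estimator_meta`). MI in bits is bounded below by 0; the
  package makes no attempt to reproduce reference MI magnitudes reported
  on unavailable data with an unspecified estimator.
* The simulator's independence claim at coupling 0 concerns the latent
  trace, not the schedule: segment baselines affect both workload and
  velocity, so independence checks must condition on the schedule (the
  tests use single-segment sessions for exactly this reason).
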