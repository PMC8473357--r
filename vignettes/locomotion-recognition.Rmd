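---
title: "Online locomotion recognition and prediction from fused sEMG and acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online locomotion recognition and prediction from fused sEMG and acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wearable lower-limb systems (exoskeletons, powered prostheses) must know
which locomotion mode the wearer is in — sitting (S), standing (ST), level
walking (LW), stair ascent/descent (SA/SD), ramp ascent/descent (RA/RD) —
and ideally which mode comes *next*, before the new steady gait begins.
Inertial signals describe the current mechanical state of the limb, so on
their own they can only recognise a transition after the movement has
changed.  Surface electromyography (sEMG) reflects the neural drive to the
muscles, which rises *before* the mechanical movement it produces
(electromechanical delay).  Fusing the two therefore promises both accurate
steady-state recognition and genuinely predictive transition detection.

`gaitfusion` implements this pipeline end to end, together with a synthetic
trial generator that makes the prediction claim testable: real recordings of
this kind are not publicly deposited, so the generator reproduces the
*statistical structure* the method relies on, including a configurable
interval by which EMG activation leads the kinematic change at every mode
transition.

## The pipeline

1. **Preprocessing.** Raw EMG is band-passed at 30–300 Hz (total order 4)
   and acceleration low-passed at 25 Hz (total order 6), both with zero-lag
   (forward–backward) Butterworth filters.
2. **Features.** A causal sliding window (default 80 ms) computes the RMS
   of each of the 14 EMG and 21 acceleration channels at every sample
   instant; the fused feature vector has 35 elements, min–max normalized
   with bounds learned on training data.
3. **Classification.** One of SVM (RBF C-SVM, one-vs-one), KNN, LDA or a
   one-hidden-layer neural network (30 nodes), trained on steady-state
   samples only, emits a raw label per sample instant.
4. **Decision layer.** The online output updates only when (a) at least
   `agreement_n` consecutive raw labels (default 100, i.e. 50 ms at
   2000 Hz) agree on a mode different from the current output and (b) the
   transition is legal under the rule table: S↔ST only via each other,
   ST→LW, LW→ any mode except S, and stairs/ramps only back to LW
   (18 allowed cells including the diagonal).
5. **Evaluation.** Steady-state recognition is scored sample-wise as
   classification accuracy `CA = 100·Ntrue/Nall` with one-vs-rest
   sensitivity/specificity macro-averaged over the seven modes.
   Each gait transition is scored by whether the upcoming steady mode is
   ever correctly output (predictive accuracy PA) and by the response time
   `RT = T_pred − T_actual`, negative when the mode is predicted before its
   onset.  `T_pred` is the start of the run of correct outputs that
   persists until onset — a transient flicker cannot claim an early
   prediction; a transition only recognised after onset still counts, with
   positive RT.

```{r, eval = FALSE}
library(gaitfusion)
trials <- simulate_cohort(tasks = 1:5, n_trials = 6, seed = 1)
spec <- classifier_spec("SVM", grid = data.frame(cost = 32, gamma = 1/35))
evaluate_cohort(trials, spec, window_ms = 80)
```

## What the generator emulates

Each trial follows one of the five scripted task sequences (e.g.
ST–LW–SA–LW–ST) on a continuous gait-cycle clock (mean cycle 1.1 s, 5%
duration jitter), with half a cycle of lead-in/out padding so that every
heel strike is an interior event.

* **EMG** = activation envelope × band-limited (30–300 Hz) unit-variance
  carrier noise + a small wide-band component.  Envelopes are hand-designed
  phase-locked curves: the proximal channels of both legs carry a tonic
  "postural code" that differs between every mode pair (bilateral, as
  postural co-activation is), the remaining channels carry raised-cosine
  bursts for the five ambulation modes.  Multiplicative envelope-on-carrier
  structure is exactly what an RMS feature assumes.
* **Acceleration** = per-channel constant gravity/posture offset plus, for
  ambulation modes, a gait-locked fundamental and second harmonic, plus
  Gaussian noise.  The per-mode offsets are graded along a path so that
  modes adjacent in the legality graph are kinematically *similar* — mode
  pairs separate much more weakly in acceleration than in the EMG code.
  This mirrors the physical situation the method exploits: during a
  transition the limb state evolves continuously between neighbouring
  modes, while the neural drive has already switched.
* **Markers.** Three anterior traces (heel, toe, pelvis); the heel-minus-
  pelvis coordinate peaks exactly once per cycle at each heel strike, which
  is what the coordinate-based heel-strike detector looks for.  The marker
  oscillation runs through the quasi-static S/ST segments too, giving the
  segmenter a uniform cycle structure over the whole trial.
* **Transitions.** Mode onsets coincide with heel strikes (a steady mode
  begins with the first heel strike on the new terrain).  Template switches
  are linear cross-fades of 100 ms (a hard switch would ring through the
  zero-lag filters and corrupt timing measurements).  Each fade *starts* at
  its nominal switch instant: the acceleration fade and the ground-truth
  label change start at the onset, the EMG fade starts `emg_lead_ms`
  earlier, so the first EMG deviation from the old mode precedes the onset
  by exactly the configured lead.

What it does **not** emulate: motion artifacts, powerline interference,
electrode lift-off, muscle fatigue, inter-subject variability, or
physiologically calibrated per-muscle activation magnitudes.  Template
margins are free design parameters, so absolute synthetic accuracies are
*not* comparable to accuracies reported on human recordings; what carries
over is the relative structure — which modality supports prediction, the
sign and rough scale of response times, and the behaviour of the decision
layer.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fs` | 2000 | Hz | sampling rate of both sensor streams |
| `cycle_duration_s` | 1.1 (± 5%) | s | typical adult gait cycle |
| `n_cycles_per_mode` | 3 | cycles | a few strides per terrain segment (stairs in such protocols are ~4 steps) |
| `emg_lead_ms` | 300 | ms | electromechanical lead of the envelope switch; the quantity the pipeline should recover |
| `transition_ramp_ms` | 100 | ms | cross-fade at template switches |
| `emg_noise_snr` | 20 | – | envelope scale (0.1 mV) over additive wide-band noise SD |
| `accel_noise_sd` | 0.05 | m/s² | accelerometer noise |
| `window_ms` | 80 (50 for LDA) | ms | sliding RMS window; the operating point of the method |
| `agreement_n` | 100 | samples | vote length; 50 ms minimum update latency at 2000 Hz |
| `train_stride` | 20 | samples | training rows are thinned (10 ms apart); online testing always streams at one-sample steps |

## Numerical and design choices

* **"Fourth-order zero-lag"** is read as the *total* effective order:
  a 2nd-order design applied forward and backward (likewise 6th = 3rd
  twice), the usual convention in gait analysis.  Signals are extended by
  odd reflection (padding bounded by three periods of the lowest corner
  frequency) before the forward–backward pass to suppress edge transients.
* **Causal windows.** RMS windows end at the decision instant; centring
  them would leak future samples and corrupt response times.
* **Half-open gait cycles** `[HSᵢ, HSᵢ₊₁)` make the switch-at-heel-strike
  boundary case unambiguous in `segment_cycles()`.  Because simulated mode
  onsets fall exactly on heel strikes, the transition cycle used for
  training exclusion and for prediction scoring is derived directly from
  the ground-truth events as the cycle *ending* at each onset
  (`transition_windows()`, `steady_state_mask()`).
* **Normalization hygiene.** Min–max bounds are fitted on training-fold
  steady rows only and applied to test data with clipping to [−0.5, 1.5];
  fitting bounds on "all activities" including test data would leak.
  Modality subsetting happens before bound fitting.
* **Vote semantics.** Agreement is counted purely on the raw-stream suffix
  (the operator is memoryless beyond `agreement_n` labels); a candidate
  blocked by the legality table does not update the output and does not
  reset anything.  The initial output mode is taken from the script's
  first mode — trials start seated or standing — rather than bootstrapped
  from the vote, which would leave the first 50 ms undefined.
* **PA is scored per transition event**, not per sample: one RT per
  transition matches how response times are reported and avoids weighting
  long transitions more heavily.
* **Classifier backends** are the standard implementations (`e1071::svm`,
  `class::knn`, `MASS::lda`, `nnet::nnet`); the contribution here is the
  protocol, feature fusion, and decision layer, not the solvers.  The LDA
  variant is plain linear discriminant analysis.  The neural network uses
  `nnet`'s compiled quasi-Newton optimiser with the stated architecture
  (one hidden layer, 30 nodes, softmax); with full-batch training the
  optimiser choice affects speed, not the fitted model class.
* **Hyperparameter search** defaults to conventional log-spaced grids
  (SVM: cost 2⁻⁵…2¹⁵, γ 2⁻¹⁵…2³; KNN: odd k ≤ 25) under stratified 5-fold
  CV; cohort-scale examples fix cost = 32, γ = 1/35, which is uncritical on
  well-separated synthetic data.
* **Degenerate inputs** are handled explicitly: constant feature columns
  normalize to zero with a warning; constant marker traces yield no heel
  strikes; fewer than two heel strikes yield no cycles; a trial with no
  transitions reports PA as absent rather than zero.

## Problem sizes

The packaged analyses run at desk scale, chosen once: cohorts of 6 trials
per task (the minimum the six-set split protocol admits), 3 gait cycles per
steady segment, and 5 cohort seeds × 5 tasks for the lead-recovery
analysis in `scripts/acceptance.R`.  Under these conditions the fused
SVM pipeline predicts transitions before onset (negative mean RT), the
EMG-only variant predicts earliest, and the acceleration-only variant
recognises transitions only after onset (positive RT) — the ordering the
fusion hypothesis implies.  The exact numbers are computed, not quoted:
run the acceptance script or `evaluate_cohort()` to regenerate them.

## Known limitations

* The decision layer imposes a hard floor of `agreement_n/fs` on update
  latency; a transition predicted less than 50 ms before onset therefore
  still produces a short burst of stale output at the start of the new
  steady segment, which is counted against online CA.
* Consecutive-agreement voting is one reading of "at least 100 previous
  windows agreed"; a 100-of-M majority variant would behave differently on
  noisy raw streams.
* Transition ground truth comes from the simulator's labels.  The marker
  model is three anterior traces only; full marker-set kinematics (e.g.
  hip angular velocity criteria for transition onset) are out of scope.
* Only RMS features are implemented; wavelet or amplitude-statistics
  features are deliberately excluded from the method's definition.
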