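# gaitfusion

Online recognition and **prediction** of human locomotion modes from fused
surface electromyography (sEMG) and lower-limb linear acceleration.

Wearable interactive systems — exoskeletons, powered prostheses — need to
know the wearer's current locomotion mode (sit **S**, stand **ST**, level
walk **LW**, stair ascent/descent **SA**/**SD**, ramp ascent/descent
**RA**/**RD**) and, for smooth transitions, the *next* mode before its
steady gait begins.  Acceleration reflects the current mechanical state of
the limb; sEMG reflects the neural drive, which rises before the movement
it produces.  `gaitfusion` implements the fusion pipeline that exploits
this: at every sample instant *i* a causal sliding window yields the fused
RMS feature vector

    X_i = { T_e1, …, T_e14, T_a1, …, T_a21 }        (35 features)

(14 EMG channels, 7 tri-axial acceleration placements), min–max normalized
and classified by SVM, KNN, LDA or a small neural network trained on
steady-state data only.  The raw per-sample stream is stabilized by an
agreement vote (the output updates only after ≥ 100 consecutive identical
labels — a 50 ms floor at 2000 Hz) combined with a transition-legality
table (S only to ST, ST only to LW, LW to anything but S, stairs/ramps only
back to LW).  Performance is scored as

    CA  = 100 · Ntrue / Nall                        (steady-state accuracy, %)
    SEi = TP/(TP+FN),  SPi = TN/(TN+FP)             (one-vs-rest, macro-averaged)
    PA  = 100 · Npred_tran / Nall_tran              (predictive accuracy, %)
    RT  = T_pred − T_actual                         (response time; < 0 = predicted early)

Because recordings of this kind are not publicly deposited, the package
ships a seedable synthetic trial generator with the statistical structure
the method relies on — gait-cycle-locked EMG envelopes on 30–300 Hz carrier
noise, smooth periodic accelerations with per-mode gravity offsets, marker
traces peaking at every heel strike, and a configurable interval
(`emg_lead_ms`, default 300 ms) by which the EMG envelope switch *leads*
the kinematic change at every transition.  That lead is what makes
prediction-before-onset possible, and recovering it is the package's core
end-to-end test.

## Worked example

Simulate a cohort of task-2 trials (ST–LW–SA–LW–ST), train an SVM on five
of the six trials per task, and stream the held-out trial through the full
online pipeline:

```r
library(gaitfusion)

trial <- simulate_trial(sim_config(task = 2, seed = 7))
trial
#> <gait_trial> 35878 samples (17.9 s @ 2000 Hz), script ST-LW-SA-LW-ST
#>   16 heel strikes, 4 mode onsets

trials <- simulate_cohort(tasks = 2, n_trials = 6, seed = 7)
spec   <- classifier_spec("SVM", grid = data.frame(cost = 32, gamma = 1/35), seed = 7)
ev     <- evaluate_cohort(trials, spec, window_ms = 80)
ev
#> <cohort_eval> SVM, fusion, 80 ms window
#>   CA 100.00%  SE 100.00%  SP 100.00%  PA 100.0%  RT -153.1 ms

head(ev$transitions$outcomes, 4)
#>   next_mode T_actual  T_pred  RT_ms predicted_before counted
#> 1        LW   3.8625  3.6940 -168.5             TRUE    TRUE
#> 2        SA   7.0920  6.9330 -159.0             TRUE    TRUE
#> 3        LW  10.5905 10.4425 -148.0             TRUE    TRUE
#> 4        ST  13.8520 13.7150 -137.0             TRUE    TRUE
```

Reading the output: every steady-state sample of the held-out trial was
recognised correctly (CA 100%), every gait transition's upcoming mode was
output before its onset (PA 100%, `predicted_before`), and on average the
online output switched to the next mode 153 ms *before* the first heel
strike on the new terrain (negative RT) — the 300 ms EMG lead minus the
costs of the 80 ms RMS window, the 100 ms activation cross-fade and the
50 ms agreement vote.  `run_window_sweep()` and
`run_modality_comparison()` tabulate the same metrics across window sizes
and across EMG-only / acceleration-only / fused feature sets, and
`run_experiment()` drives everything from a single YAML/JSON config (see
`inst/scripts/gaitfusion-cli.R` for a shell entry point).

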