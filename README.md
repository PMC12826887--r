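# ppgrisk

Morphological analysis of photoplethysmogram (PPG) pulse waveforms and
survival modelling of the cardiovascular risk their shape carries.

The fingertip PPG is the optical blood-volume pulse recorded by pulse
oximeters and wrist wearables. Its contour is shaped by the interaction of
left-ventricular ejection with the peripheral vasculature, so geometric
features of a single ensemble-averaged beat — timing of the systolic peak,
the area under the systolic limb, the alternating a–e waves of the second
derivative — are candidate prognostic markers for incident cardiovascular
disease, beyond blood pressure and the classical risk factors.

`ppgrisk` implements that analysis end to end, for epidemiologists and
signal-processing researchers working with beat-resolved PPG plus
time-to-event follow-up:

1. **Waveform processing** — beat segmentation (foot-to-foot), ensemble
   averaging over a 10–15 s window, min–max amplitude normalization, and
   smoothed polynomial-filter (Savitzky–Golay) first/second derivatives.
2. **Fiducial detection** — systolic peak, maximum upslope (ms), dicrotic
   notch (with second-derivative e-wave fallback), diastolic peak (with
   inflection fallback), and the a–e waves of x″.
3. **20 morphological indices** — periods and intervals (T, CT, DT,
   t_systole, t_b–c, t_b–d), areas (A1, A2), derivative amplitudes (ms,
   a–e), and composites:
   AGI_mod = (b − c − d)/a,
   slope_b–c = (c − b)/((t_c − t_b)·a),
   IPAD = A2/A1 + d/a,
   and the diastolic decay constant k from an exponential fit of the tail.
4. **Outcome handling** — ICD-9/10 prefix classification (CVD, CHD, MI,
   heart failure, stroke, hypertension), first-event/censoring logic with a
   10-year horizon, and cohort-flow accounting.
5. **Survival modelling** — per-SD covariate-adjusted Cox models
   (`survival`), elastic-net penalized Cox with 5-fold CV over the mixing
   parameter (`glmnet`), scaled Schoenfeld diagnostics, Kaplan–Meier
   quartile curves.
6. **Prediction evaluation** — Harrell's C (= Somers' Dxy/2 + 0.5) with
   bootstrap CIs, a paired-bootstrap Z-test for ΔC, the 10-rung nested
   model ladder (age → … → + PPG indices) on a held-out 20% split, and
   age-stratified comparisons.
7. **Synthetic truth** — a four-Gaussian continuous beat model with
   analytic/quadrature ground truth for every fiducial and area, beat-train
   generation with noise and jitter, and a Weibull proportional-hazards
   cohort simulator with known log-hazards, so every stage is testable
   against an oracle.

## Worked example

```r
library(ppgrisk)

## a noisy 15-beat synthetic recording -> one analysis-ready beat
tr    <- generate_beat_train(beat_params(), n_beats = 15, sampling_rate = 250,
                             noise_sd = 0.02, period_jitter_sd = 0.02, seed = 42)
seg   <- segment_beats(tr$samples, 250)
pulse <- ensemble_average(seg$beats, 1/250)
pulse
#> <pulse_wave> 204 samples, dt = 0.004 s, T = 0.81 s

round(unlist(extract_all(pulse)[, c("T","CT","t_systole","A1","c","AGI_mod","IPAD","k")]), 4)
#>        T        CT t_systole        A1         c   AGI_mod      IPAD         k
#>   0.8100    0.1400    0.4040    0.1835  160.3611   -1.2610    1.1927    8.7287
```

`T` is the beat period (s), `CT` the foot-to-systolic-peak time (s),
`t_systole` the foot-to-notch time (s), `A1` the systolic area (s), `c` the
mid-late systolic curvature wave of x″ (1/s²), and `k` the diastolic decay
rate (1/s).

```r
## a synthetic cohort whose hazard loads on t_systole, A1 and c
co <- simulate_cohort(cohort_spec(n = 5000,
        beta = c(t_systole = log(1.43), A1 = log(0.79), c = log(0.80))), seed = 42)

## covariate-adjusted per-SD hazard ratio for the c wave
fit_adjusted_cox(co, "c")$table[1, ]
#>   term   coef     se    HR ci_low ci_high        p
#> 1    c -0.199 0.0461 0.819  0.748   0.897 1.55e-05

## elastic-net selection and held-out concordance
pn   <- fit_penalized_cox(co, split_seed = 42)
pn$selected
#>  [1] "T" "DT" "t_systole" "t_bc" "dia_amp" "A1" "A2" "ms" "c" "k"
test <- co[pn$split$test, ]
lp   <- risk_scores(pn$refit, test)
bootstrap_c_ci(test$time, test$event, lp, B = 200, seed = 42)[c("c", "ci")]
#> held-out C = 0.670 (95% CI 0.619-0.712)
```

The adjusted HR of 0.82 per SD recovers the simulated log-hazard of
ln 0.80; the selected set contains the three true signal indices (plus
correlated passengers, as CV-tuned elastic nets do); the held-out C of 0.67
is the discrimination of the refit model on the 20% test split.

A command-line interface wraps the same pipeline
(`exec/ppgrisk simulate | extract-features | fit-cox | fit-coxnet |
evaluate-ladder | km-plot`).

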