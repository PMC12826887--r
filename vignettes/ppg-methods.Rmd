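---
title: "Pulse-waveform indices and cardiovascular risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-waveform indices and cardiovascular risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgrisk)
```

## The measurement model

A fingertip photoplethysmogram is recorded for tens of seconds, segmented
into beats at the waveform foot, ensemble-averaged over a 10–15 s window,
and min–max normalized so that one representative beat lives on
amplitude scale $[0,1]$ with its foot at $t = 0$ and duration $T$ seconds.
Because the raw PPG amplitude depends on local perfusion and sensor
coupling, only the *shape* of the normalized beat is analysed; every index
the package emits is invariant to multiplying the raw signal by a positive
constant (a property the test suite asserts across random beats).

Derivatives are estimated with a Savitzky–Golay filter: a least-squares
polynomial is fit in a sliding window and differentiated analytically.
Defaults are a 50 ms window and polynomial order 4. Order matters here:
with order 3 the positions of the second-derivative extrema are biased by
up to ~3 ms on smooth synthetic beats, which exceeds the 2-sample
localization tolerance the test suite holds the pipeline to; order 4
removes that bias at negligible variance cost on ensemble-averaged beats.
Both the window and order are arguments, since the upstream device
filtering of any particular recording system is rarely documented.

## Fiducial points

On the normalized beat $x$ and its derivatives $x'$, $x''$:

* systolic peak: global maximum (earliest sample on ties);
* ms: maximum of $x'$ on the rising limb $[0, t_{sys}]$;
* a–e waves: alternating extrema of $x''$ — a the first maximum after the
  foot, b the first minimum after a, then c, d, e; a missing wave (a
  monotone $x''$ segment) is flagged, never imputed, and every index that
  depends on it is reported as missing;
* dicrotic notch: earliest local minimum of the (smoothed) waveform after
  the systolic peak; when no minimum exists — the merged-diastole contour
  typical of older or stiffer circulations — the e-wave time is used and
  flagged as a fallback;
* diastolic peak: largest local maximum after the notch; for monotone
  diastolic decay the first inflection of the decay ($x'' = 0$, or the
  flattest-curvature point when the decay is purely convex) is used and
  flagged.

The notch and diastolic scans run on a smoothed copy of the beat (same
filter as the derivatives). On a noisy ensemble average, residual ripples
of a few parts per thousand otherwise spawn spurious local minima right
after the systolic peak; scanning the smoothed contour and reading
amplitudes off the raw samples removes that failure mode without biasing
clean beats (the noise-free localization checks still pass at 2 samples).

## The 20 indices

Timing: $T$, $CT$ (foot → systolic peak), $t_{systole}$ (foot → notch),
$DT$ (systolic → diastolic peak), $t_{b\text{-}c}$, $t_{b\text{-}d}$.
Amplitudes: dia$_{amp}$, ms, and the raw $x''$ amplitudes a–e (1/s²).
Areas: $A_1$ (foot → notch) and $A_2$ (notch → end), trapezoids of the
normalized beat on the sample grid, in seconds. Composites:

$$\mathrm{AGI_{mod}} = \frac{b - c - d}{a}, \qquad
  \mathrm{slope}_{b\text{-}c} = \frac{c - b}{(t_c - t_b)\,a}, \qquad
  \mathrm{IPAD} = \frac{A_2}{A_1} + \frac{d}{a},$$

and the diastolic decay constant $k$: the least-squares rate of
$x(t) \approx A e^{-k (t - t_{dia})} + C$ over the diastolic tail. The
offset $C$ is estimated jointly with $A$ and $k$ (profiled linearly for
each candidate $k$, one-dimensional search over $k \in [0, 60]$ 1/s). An
alternative strategy that pins $C$ at the end-of-beat amplitude is
available, but it is biased upward whenever the tail has not reached its
asymptote by the pulse end — on a pure $e^{-3t}$ tail it returns ~3.5
instead of 3 — so the free-offset fit is the default.

Heart rate and the height-scaled stiffness index SI are deliberately not
emitted: period is used in preference to heart rate, and DT (the interval
SI is derived from) is emitted instead of SI. Exact formulas for
AGI$_{mod}$ and $k$ vary across extraction toolboxes; the definitions above
are documented defaults, exposed as configurable strategies, not claims of
equivalence to any particular proprietary implementation.

## Synthetic ground truth

The beat generator is a sum of four Gaussian lobes (systolic, reflected,
mid-late systolic, diastolic) multiplied by a smooth exponential decay
that switches on past the diastolic lobe via a softplus ramp, making the
model $C^\infty$. Truth is computed on the *continuous* function — peak
and extremum times by dense-grid scan plus golden-section refinement,
areas of the normalized contour by adaptive quadrature — never on the
sample grid, so grid-level discretization shows up as error of the
pipeline, not of the oracle.

Defaults: period 0.8 s (75 bpm), 250 Hz sampling, component amplitudes
(1.00, 0.42, 0.18, 0.24), centers (0.125, 0.220, 0.310, 0.445) s, widths
(0.042, 0.060, 0.042, 0.075) s, decay 3/s. These were chosen once so that
the canonical beat exhibits every fiducial (clear notch, distinct
diastolic peak, five alternating $x''$ extrema) at physiological timing,
and were not revisited afterwards. A `morph_c` multiplier scales the third
lobe: increasing it deepens the mid-late systolic curvature, and the
extracted c-wave amplitude responds strictly monotonically — the package's
reproduction of the simulation that motivates reading c as a curvature
measure.

Two features of real recordings the generator deliberately does **not**
emulate: baseline wander/motion artifact (out of scope; no artifact-
rejection ML), and a non-flat pre-foot baseline. The second has a testable
consequence: the Gaussian tail decays to sub-1% of pulse amplitude over
the last ~150 ms of diastole, so under additive noise at 20 dB SNR the
pre-upstroke minimum is noise-dominated and *no* minimum-based foot
detector can localize the foot to 2 samples there. Measured with the
shipped detector (smoothed last-local-minimum before the upslope, refined
on the raw samples): noise-free feet are exact to 1 sample; at 20 dB the
median error is ~2 samples with occasional 5–10 sample excursions, which
the ensemble average then absorbs (averaged-beat index errors remain
smaller than single-beat errors, as the suite verifies). A green foot test
therefore establishes clean-signal correctness and bounded noisy-signal
degradation, not sample-exact localization under noise.

The cohort simulator draws the 20 indices as standard normals with
loading $r = 0.3$ on standardized age (confounding) and exchangeable
residual correlation $\rho = 0.2$ (a shared latent factor), covariates
with community-cohort marginals (age 56.8 ± 6.1 truncated to 40–69, 52%
women, 10% smokers, 5% diabetes, SBP 138 ± 18 mmHg, 20% on BP
medication), and event times from a Weibull proportional-hazards model
$S(t\mid x) = \exp[-(t/\lambda)^{\kappa} e^{\beta^\top x}]$ inverted by
$t = \lambda(-\log U e^{-\beta^\top x})^{1/\kappa}$, with shape
$\kappa = 1.2$, scale $\lambda = 80$ years (≈8% event rate over the
10-year administrative horizon), and the exponential model available as
the $\kappa = 1$ special case. Default covariate log-hazards are ordinary
epidemiological magnitudes (age 0.55/SD, male 0.40, smoking 0.45,
diabetes 0.55, SBP 0.25/SD, …); index log-hazards default to zero and are
set by the caller — recovery tests use ln 1.43 ($t_{systole}$), ln 0.79
($A_1$), ln 0.80 (c).

## Survival modelling choices

* **Ties**: Efron approximation (the less biased default; simulated times
  are continuous, so this matters only for user data).
* **Per-SD reporting**: each index is standardized over the analysis
  sample; `risk_scores()` re-applies the training standardization to new
  data so held-out evaluation is well defined.
* **Elastic net**: indices are penalized, the nine classical risk factors
  enter unpenalized (`penalty.factor = 0`). The mixing parameter is
  grid-searched over {0.1, 0.3, 0.5, 0.7, 0.9, 1.0} by 5-fold CV of the
  partial-likelihood deviance with a shared fold assignment; the penalty
  strength is the deviance-minimizing $\lambda$. The one-SE rule is
  available but defaults off: with a fully unpenalized adjustment set the
  covariates dominate the deviance scale and the one-SE band deletes
  every index. Selected indices are refit unpenalized (with the
  covariates) for reportable Wald CIs, since penalized coefficients carry
  no standard errors; whether published CIs for penalized models come
  from such a refit is usually unstated, and both routes are kept.
  CV-min selection overselects by design — correlated passengers of true
  signals enter with small coefficients — so selection tests assert that
  the true support is *contained* in the selection, not equal to it.
* **Proportional-hazards diagnostics**: scaled Schoenfeld residuals with
  the Grambsch–Therneau correlation-with-time test (`survival::cox.zph`,
  identity transform), since graphical checks need a numeric counterpart
  in tests.
* **Quartiles**: nearest-rank with stable tie-breaking, so group sizes
  differ by at most one.

## Concordance and incremental value

Harrell's C is authored in-package (and dual-checked in the tests against
an exhaustive $O(n^2)$ pair-enumeration oracle, never against another
library): a pair is usable when its member with the strictly shorter
observed time has an event; tied observed times are unusable; tied risk
scores count ½. On uncensored data this equals Somers' $D_{xy}/2 + 0.5$
for (risk, time). Risk scores are Cox linear predictors — "higher
predicted survival" is implemented as its negation.

Confidence intervals are percentile bootstrap over participants (1000
replicates by default, seeded); degenerate resamples with no usable pairs
are redrawn and counted. $\Delta C$ between two models evaluated on
identical rows uses the paired bootstrap: $Z = \Delta C / SE_{boot}$ with
a two-sided normal p, which is invariant under strictly monotone
transforms of either score. Evaluation is fit-on-80%/score-on-20% by
default; in-sample values can be requested alongside.

One calibration subtlety the test suite documents: if "CRF + indices" is
an *unpenalized* refit of all 20 indices at small n (~130 training
events), its held-out $\Delta C$ under the pure-noise null is genuinely
negative (≈ −0.02) — overfitting 20 noise coefficients costs real
discrimination, and the Z-test correctly rejects in ~13% of runs. That is
a property of the protocol, not a miscalibration of the test (the
bootstrap SE matches the sampling SD). The package's panel procedure —
elastic-net selection then refit — restores the null ($\Delta C \approx
0$) and the measured test size is 5% at n = 2000 over 200 seeds.

The model ladder adds, in fixed order: age, sex, ethnicity, BMI, smoking,
diabetes, TC/HDL, BP medication, SBP, and finally the PPG indices, each
rung reporting C, its CI, and $\Delta C$ versus the previous rung. The
age-stratified evaluation repeats the CRF vs CRF+PPG comparison within
age bands (<50, 50–64, ≥65), fitting within stratum.

## Numerical conventions and edge cases

* Ties in any argmax scan resolve to the earliest sample.
* Trapezoid integration on the sample grid; at 250 Hz its discretization
  error is ~10⁻³·s, at 1000 Hz below 10⁻⁴, which is why quadrature-level
  area checks run on a 1 kHz grid.
* Pipeline-vs-continuous-truth agreement for second-derivative
  *amplitudes* is limited to ~1e-3 by smoothing attenuation (times are
  much tighter); composite checks (IPAD) are asserted at 5e-3.
* Constant beats, empty search windows, all-censored cohorts, degenerate
  quartiles and empty age strata raise (or flag) rather than return
  numbers; batch extraction converts per-beat failures into flagged NA
  rows and never aborts.
* All simulation, resampling and splitting is seeded; identical seeds
  give bit-identical outputs.

## Known limitations

* Fiducial constants (search windows, fallback rules) are sensible
  defaults, not a validated clinical algorithm; no claim of equivalence
  to any published extraction software.
* The cohort simulator reproduces documented marginals and one
  confounding structure, not the joint distribution of any real cohort;
  a green recovery test shows the estimator works under the stated
  model, nothing more.
* Exact-support selection consistency is not a property of CV-tuned
  elastic nets under correlated designs and is not claimed.
* Competing risks are handled by cause-specific censoring only; no
  time-varying coefficients; no reclassification (NRI/IDI) metrics.
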