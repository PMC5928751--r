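---
title: "Methods: dual-modality localization of the anterior/posterior STG boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality localization of the anterior/posterior STG boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgboundary)
```

## The scientific problem

The superior temporal gyrus (STG) hosts a sharp functional division:
cortex anterior to the posterior margin of Heschl's gyrus responds more
strongly to audiovisual speech whose auditory component is clear, while
cortex posterior to that landmark responds as strongly, or more strongly,
to speech whose auditory component is noisy — the signature of multisensory
regions that recruit visual speech to compensate for degraded audition.
`stgboundary` implements the full analysis chain that localizes this
boundary from two very different measurements — electrocorticographic
(ECoG) broadband high-gamma power and event-related BOLD fMRI — together
with the forward model that links them. Because the raw clinical recordings
behind such analyses cannot be redistributed, the package is built around a
synthetic-data generator that plants a known boundary, so that every stage
of the pipeline can be validated by parameter recovery rather than by
eyeballing.

## The gyrus as a one-dimensional strip

The length analysis is intrinsically one-dimensional: statistics are binned
every 1 mm from the anterior tip to the posterior end of the gyrus. The
package therefore models the STG as a straight strip (default 100 mm) with
positions in mm, replacing cortical-surface meshes. Two landmarks live on
the strip: the anatomical boundary (default 70 mm), standing in for the
posterior-most point of Heschl's gyrus, and the planted functional boundary
(default 68 mm) where the generating clear-minus-noisy response difference
crosses zero. An affine map `y = 40 - position` reports positions in a
standard-space anterior-posterior coordinate; the defaults place the
anatomical landmark at y = -30 and the planted boundary at y = -28, the
region of standard space where this boundary is reported in group studies.
The planted boundary lies in the posterior third of the strip, which is
where the detector searches.

## What the generator emulates — and what it does not

`default_sim_params()` fixes the study conditions:

* **Design.** Rapid event-related runs of 160 volumes at TR 1.5 s, each
  with 48 3-s audiovisual word trials, 12 per condition (auditory
  clear/noisy crossed with visual clear/blurred), 96 s of fixation baseline
  per run, five runs (60 repetitions per condition). Onsets are randomized
  on the TR lattice by shuffling trial blocks against single-TR baseline
  fillers — a simple stand-in for an optimized schedule; the counts and
  non-overlap are exact for every seed.
* **ECoG.** 2 kHz recordings. Each electrode carries a band-limited
  70–110 Hz carrier of fixed baseline power; on every trial the carrier is
  gain-modulated so that its instantaneous band power exceeds baseline by
  exactly `amplitude x envelope(t)` percent. Anterior electrodes peak at
  300% (auditory-clear) vs 110% (auditory-noisy); posterior electrodes at
  110% vs 190%. The posterior pair is a fixture choice — group reports give
  posterior amplitudes only qualitatively (noisy > clear) — as is the
  envelope: silent for the first 100 ms after auditory onset, rising to its
  peak at 200 ms, sustained through the word to 1.0 s, gone by 1.4 s. A
  gamma-shaped transient that peaked at 200 ms and decayed immediately
  would be attenuated ~20% by the 200-ms spectral-analysis window; the
  sustained plateau matches reported word responses and keeps the planted
  amplitude an exact generative quantity. Background noise is pink
  (1/f) with the 65–115 Hz range notched out, so that within-band power is
  carried entirely by the modulated carrier; a common-mode 60 Hz line
  component is added, and 24 off-strip reference channels emulate the rest
  of a clinical array (with too few channels, common average referencing
  would subtract an appreciable fraction of each electrode's own signal).
* **BOLD.** Voxel columns every 2 mm along the strip, 3 voxels deep, plus
  off-gyrus voxels. Per-condition response amplitudes follow a logistic
  anterior-to-posterior profile (anterior 0.37%/0.24% signal change for
  clear/noisy, posterior 0.33%/0.40%, taken from the coefficient structure
  of the group mixed-model tables); amplitudes multiply a ground-truth
  hemodynamic kernel evaluated at each trial onset, about a raw intensity
  baseline of 1000 (an arbitrary scanner unit, removed again by
  percent-signal scaling). Noise is AR(1) (coefficient 0.3, innovation SD
  0.5% — chosen to give realistic single-voxel t-values), per-run quadratic
  drift (up to ±0.6%), and a small leak of six smooth motion regressors
  into the data.
* **Transition geometry.** Both modalities share a logistic transition of
  width 4 mm, so the contrast flips completely within ~10 mm. The logistic
  center is solved per modality so that the clear-minus-noisy difference
  crosses zero exactly at the planted boundary even though the anterior and
  posterior difference magnitudes are unequal.
* **Behavior.** Bernoulli word-report accuracy of 0.99 (auditory-clear),
  0.87 (noisy + clear visual) and 0.69 (noisy + blurred visual).

The generator does **not** emulate cortical folding, epileptiform or
movement artifacts, spatially correlated BOLD noise, susceptibility
dropout, or behavioral lapses/learning. Passing recovery tests therefore
demonstrates the correctness of the analysis chain under the stated
statistical structure, not robustness to every pathology of real data.

## ECoG quantification

The chain is common average referencing (across the full array including
reference channels), line-noise removal by per-segment sine/cosine
regression at 60 Hz (which removes exactly two degrees of freedom per
second and spares broadband 70–110 Hz power, unlike a wide IIR notch),
epoching around auditory onset, and sliding-window multitaper spectral
estimation: 200 ms windows, 10 ms steps, 3 sine tapers (~±5 Hz effective
smoothing, matched to the 5 Hz Rayleigh resolution of the window), power
averaged over 70–110 Hz and expressed as percent change relative to the
baseline window (−500 to −100 ms). The baseline divisor is the electrode's
mean baseline power *across trials*: a per-trial divisor estimated from a
400-ms window has ~20% relative error, which both inflates the variance of
every trace and biases the ratio upward; a common divisor removes the bias
while preserving the per-trial baseline values needed by the inclusion
test. The window-rate estimate is interpolated to a 1 ms output grid.

Electrode inclusion mirrors the selection of stimulus-responsive sites: a
paired t-test across trials of log response-window power (0–500 ms) against
log baseline-window power, included at p < 10⁻³. The log stabilizes the
variance of power estimates. Per-electrode condition contrasts pool the two
auditory-clear conditions against the two auditory-noisy conditions with a
Welch unequal-variance t-test (the reported per-condition SEMs differ more
than two-fold, so a pooled-variance test would be miscalibrated);
Welch–Satterthwaite degrees of freedom.

## BOLD modelling

Voxel series are rescaled to mean 100 so betas read as percent signal
change. Two designs are fitted by ordinary least squares:

* a **canonical block design** — one regressor per condition: the trial
  train (one event per 3-s word, treated as a 2-s neural block) convolved
  with a unit-peak kernel (gamma-variate, shape 4, scale 1.1 s, convolved
  with a 2-s boxcar), peaking 4.5–6 s after onset — plus six motion
  regressors: the printed ten-regressor model. The clear-vs-noisy contrast
  applies the weights (+1, +1, −1, −1) in the fixed condition order.
* a **tent (FIR) design** — per condition, one piecewise-linear knot per TR
  across 0–15 s: 11 knots, 44 condition columns, 50 model regressors with
  the motion columns. The knot betas are the deconvolved response shape. A
  0–30 s window with 21 knots serves slow localizer runs, summarized as the
  mean of the 4.5, 6 and 7.5 s knot betas.

Two modelling choices go beyond the printed regressor counts and are
deliberate. First, per-run polynomial baselines (intercept, linear,
quadratic) are always added as extra nuisance columns; quadratic detrending
is standard for four-minute runs and absorbs the simulated drift. They are
excluded from `n_model_regressors`, following the convention of not
counting baseline polynomials as regressors. Second, the tent basis keeps
all 11 knots free per condition (giving the printed 44 regressors of
interest) rather than pinning the endpoint knots to zero as the
conventional zero-anchored tent basis would; the t = 0 knot of a response
that genuinely starts at zero is estimated at ~0 anyway.

The omnibus F tests all condition columns jointly (full vs reduced model);
voxels with zero residual variance are flagged and reported with infinite-t
sentinels rather than NaNs.

### The generative kernel vs the comparison kernel

The BOLD simulator and the ECoG→BOLD forward model both use the package's
double-gamma constructor, with different parameters, and the distinction is
deliberate. The forward model uses the canonical comparison kernel (peak
6 s, undershoot minimum at 16 s, peak/undershoot ratio 4). The simulator's
ground-truth impulse kernel is faster — peak 5 s, undershoot minimum at
10.5 s, ratio 4, narrower lobes (shape 9) — because measured single-word
STG responses peak between 4 and 6 s with their post-stimulus undershoot
at ~10.5 s, and the deconvolved FIR estimates should reproduce that shape.
The comparison kernel is an analysis convention, not a claim about the
participants' empirical hemodynamics; using it as the generative truth
would produce FIR peaks near 7 s, which real data do not show.

Each simulated trial's response is not the bare impulse kernel but its
convolution with the same sustained neural envelope that drives the ECoG
generator (rise at 100–200 ms, plateau through 1.0 s), renormalized to
unit peak (`bold_response_kernel()`): neural activity during a 3-s word is
extended in time, and the BOLD response inherits that width. This matters
for the forward model — the prediction convolves the measured
(envelope-shaped) high-gamma timecourse with the comparison HRF, so a
generator that ignored the neural duration would make the actual FIR
systematically narrower than any prediction and cap the honest
predicted-vs-actual correlation well below what matched widths give. The
residual shape difference between the fast generative kernel and the
canonical comparison kernel still keeps pipeline correlations below the
controlled-recovery ceiling, which is expected and documented rather than
tuned away.

## Double-gamma HRF construction

Only three descriptors of the canonical HRF are specified: peak time,
peak-to-undershoot delay, and peak/undershoot amplitude ratio. The package
therefore builds the kernel as the difference of two gamma-density lobes
and *calibrates* it so the three descriptors hold exactly as realized
properties of the sampled kernel: a fixed-point iteration adjusts the two
lobe modes (because overlapping lobes shift each other's extrema) while the
mixing coefficient is solved by root finding at every step (the realized
ratio is monotone in it). The lobe shape defaults to 6 and escalates
automatically when the requested extrema are too close to be resolved by
wide lobes. The kernel is sampled at 1 ms, has value 0 at t = 0, and unit
peak.

## Boundary detection and ROIs

The unthresholded clear-vs-noisy t-map is sampled onto surface nodes (15
equal steps along the local thickness, nearest-voxel sampling, averaged),
binned at 1 mm, and scanned anterior→posterior within the posterior third
of the strip for the first sign change relative to the previous non-empty
bin. Numerical conventions, all of which matter in degenerate cases:

* the crossing bin is the posterior bin of the sign-changing pair, and its
  lower edge is the reported position;
* a bin mean of exactly zero counts as a crossing, and that bin is
  reported;
* empty bins are skipped — the comparison is against the nearest preceding
  non-empty bin, so sparse coverage cannot fabricate crossings;
* the initial reference sign is the dominant sign of the anterior
  two-thirds of the profile; if the profile has already flipped when the
  posterior third begins (the crossing completed at or just before the
  third under noise), the third's first non-empty bin is reported rather
  than declaring no boundary;
* if the profile never changes sign, no functional boundary is reported
  and downstream stages fall back to the anatomical landmark;
* only the first crossing is reported, even if the profile re-crosses.

The "posterior third" is computed on the full strip length; the reference
extent is otherwise unspecified and the full labelled gyrus length is the
natural reading. ROIs are boundary-relative: anterior = voxels in
[boundary − 30 mm, boundary), posterior = [boundary, boundary + 15 mm],
both filtered to voxels with omnibus F > 5 (mirroring the inclusion of only
responsive recording sites) and clipped with a warning at strip ends.

## Forward model

The grand-mean high-gamma percent-change timecourse of a region × auditory
condition is convolved at 1 ms with the comparison HRF (a continuous-time
convolution: the discrete sum is multiplied by dt, so the output scale is
ECoG% and an amplitude of hundreds of ECoG% maps onto tenths of a BOLD%,
as the reported conversion factors do), then sampled at stimulus-locked
multiples of the TR by nearest-sample decimation — no anti-alias filter,
because the convolved signal is already smooth on the seconds scale. The
single free parameter per curve is the scale divisor minimizing
`sum((pred/s - actual)^2)`, found by bounded minimization of the SSE over
s ∈ (10⁻⁶, 10⁶) on a log grid and cross-checked against the closed form
`<pred,pred>/<pred,actual>`; a curve whose inner product with the
prediction is non-positive is flagged unreliable rather than silently
fitted. Correlations between predicted and actual curves are computed over
the 11 TR samples spanning 0–15 s, matching the tent-window grid; each
region × auditory condition gets its own scale, and the summary conversion
factor is their arithmetic mean.

## Group statistics

The mixed model is `response ~ location * auditory * visual +
(1 | participant)` with treatment coding referenced to the anterior,
auditory-clear, visual-clear cell, fitted by lme4 with Satterthwaite
degrees of freedom via lmerTest (reported group dfs are fractional, which
pins down the approximation family). The random-effects structure is not
fully determined by the reported tables; a participant-level random
intercept is used because electrodes (ECoG) and hemispheres (fMRI) within
a participant are not independent, and it reproduces the reported pattern
of fractional baseline df with near-residual contrast df. On balanced
complete data the fixed-effect point estimates coincide with OLS, which the
test suite asserts. The behavioral comparison of the two auditory-noisy
conditions (identical auditory input, different performance) is a paired
t-test across participants; the test family behind the reported p-value is
unstated, and a paired t across participants is the conventional choice.

## Problem sizes and numerical tolerances

The test-suite simulations use desk-scale sizes chosen to keep each
property statistically decisive: boundary recovery over 20 seeds at the
full 5-run design (median absolute error ≤ 2 mm against the planted truth);
mixed-model recovery at the reported unit count (28 units, 8 cells) over
500 replicates with generating values taken from the reported
electrode-level coefficients; electrode-inclusion calibration at 10⁴ null
electrodes with per-trial powers drawn from the averaged-periodogram
(scaled chi-square) family the spectral chain produces — running the full
2 kHz multitaper chain on 10⁴ electrodes would add nothing to the
calibration claim, which concerns the test statistic, not the spectral
estimator. Amplitude-recovery assertions on the spectral chain use a 15%
tolerance at 40 trials/group (carrier-power sampling noise) and 2% for
deterministic tone inputs; OLS is checked against normal equations at
1e-8 relative; HRF descriptors are exact to the 1 ms sample.

## Known limitations

* The strip geometry has no curvature, no folding, and a single thickness
  axis; volume-to-surface sampling is nearest-voxel, not trilinear.
* The ECoG generator plants percent-change amplitudes directly; it does not
  model spike-field artifacts, electrode impedance drift, or reference
  contamination beyond the common-mode line term.
* The mixed model fits a random intercept only; random slopes (and
  hemisphere-within-participant nesting for fMRI) are not identifiable at
  the simulated participant counts and are not attempted.
* Scale-factor fits assume the predicted and actual curves share their
  time base exactly; no latency parameter is fitted.
* With very few electrodes or runs the mixed models can be singular; the
  fits are flagged rather than suppressed.
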