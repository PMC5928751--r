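# stgboundary

Dual-modality localization of the functional boundary between anterior and
posterior superior temporal gyrus (STG).

## The problem

The STG splits into two functionally distinct zones at the posterior margin
of Heschl's gyrus: anterior cortex responds more strongly to audiovisual
speech with a *clear* auditory component, posterior cortex responds as
strongly or more strongly when the auditory component is *noisy* (and
visual speech must carry the load). `stgboundary` implements the complete
analysis chain that localizes this boundary from two kinds of measurement —
intracranial ECoG broadband high-gamma power (70–110 Hz) and event-related
BOLD fMRI — plus the forward model that links them, for researchers who
want a tested, reusable version of this pipeline or a validated reference
to compare their own against.

Because the clinical recordings behind such analyses cannot be shared, the
package ships a first-class synthetic-data generator that plants a known
boundary: every stage is validated by recovering planted parameters.

## What it computes

* **ECoG**: common average referencing, regression-based 60 Hz removal,
  epoching, sliding multitaper 70–110 Hz power as percent change from a
  pre-stimulus baseline (−500 to −100 ms), electrode inclusion at
  p < 10⁻³ (paired t of log response vs baseline power), and per-electrode
  Welch contrasts of clear- vs noisy-auditory trials.
* **fMRI**: percent-signal scaling to voxel mean 100; a 10-regressor
  canonical-block GLM (4 conditions + 6 motion) with the clear-vs-noisy
  general linear test `(+1, +1, −1, −1)`; a 50-regressor tent/FIR
  deconvolution (11 knots over 0–15 s at TR 1.5 s); omnibus-F voxel
  filtering (F > 5); a 21-knot 0–30 s localizer window summarized by the
  mean beta at 4.5/6/7.5 s.
* **Boundary**: the clear-vs-noisy t-map sampled to surface nodes (15
  thickness steps), binned at 1 mm anterior→posterior, and the first
  zero-crossing in the posterior third reported as the functional boundary;
  compared against the anatomical landmark in standard-space y.
* **Forward model**: a double-gamma HRF calibrated so its printed
  descriptors hold exactly (peak 6 s, undershoot 16 s, peak/undershoot
  ratio 4, unit peak); high-gamma timecourses convolved at 1 ms,
  downsampled to the TR grid, and fitted with a single per-condition scale
  divisor s minimizing Σ(pred/s − actual)², cross-checked against
  ⟨pred,pred⟩/⟨pred,actual⟩.
* **Group statistics**: `response ~ location × auditory × visual +
  (1 | participant)` with Satterthwaite df (lmerTest), behavioral accuracy
  summaries, and paired boundary comparisons.

## Worked example

One synthetic hemisphere, simulated and analyzed:

```r
library(stgboundary)
gyrus   <- make_gyrus()                      # 100 mm strip, landmark 70 mm, planted boundary 68 mm
sched   <- make_event_schedule(n_runs = 5, seed = 1)   # 48 trials/run, 96 s baseline/run
session <- simulate_bold(gyrus, sched, seed = 1)
psc     <- scale_to_psc(session$series)
fit     <- fit_glm(psc, build_block_design(sched, session$motion))
con     <- contrast_clear_vs_noisy(fit)
nodes   <- sample_volume_to_surface(con$t, session$voxels, gyrus)
profile <- bin_profile(nodes$value, nodes$position_mm, length_mm = gyrus$length_mm)
estimate_boundary(profile, gyrus)
#> <boundary_estimate> functional 71 mm (y = -31), anatomical 70 mm (y = -30), distance 1 mm
```

The detected zero-crossing lands 3 mm from the planted boundary (68 mm) on
this seed; across seeds the median error is ≤ 2 mm. The deconvolved
response of the anterior ROI shows the expected hemodynamic shape — peak
in the 4–6 s window, undershoot at 10.5 s, amplitude in the 0.2–0.4%
range for a single word:

```r
tent <- fit_glm(psc, build_tent_design(sched, session$motion))
rois <- define_rois(68, session$voxels, fit$omnibus_f)
fir  <- estimate_hrf_tent(tent, "AclearVclear", voxels = rois$anterior)
round(setNames(fir$mean, fir$time_s), 3)
#>      0    1.5      3    4.5      6    7.5      9   10.5     12   13.5     15
#> -0.020 -0.008  0.040  0.239  0.358  0.192 -0.014 -0.089 -0.073 -0.046 -0.020
```

The full pipeline (4 ECoG participants, 6 fMRI participants × 2
hemispheres at the default configuration) runs in a few minutes:

```r
report <- run_pipeline(default_pipeline_config(seed = 1), output_dir = "out")
#> functional y: -28.7 +/- 1.7   (planted truth -28; anatomical landmark -30)
#> mean ECoG%-per-BOLD% conversion: 792
#> word-report accuracy: 0.99 (A-clear), 0.86 (A-noisy/V-clear), 0.69 (A-noisy/V-blur)
```

The mixed-model tables in `report$lme_ecog` / `report$lme_fmri` recover the
planted factorial structure: strong negative auditory-noise main effects, a
strong positive posterior × auditory-noise interaction, and null
visual-blur terms.

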