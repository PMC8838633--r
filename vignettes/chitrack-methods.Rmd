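---
title: "Simulating and analysing camera-based jugular venous monitoring"
author: "chitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing camera-based jugular venous monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitrack)
```

## The problem

Internal jugular vein (IJV) volume tracks central venous filling: it distends
under a cephalad fluid shift (head-down tilt, HDT) and empties under central
hypovolemia (lower-body negative pressure, LBNP). The clinical reference for
IJV volume is ultrasound cross-sectional area (CSA), which needs a trained
operator and skin contact. A near-infrared camera can instead quantify
per-pixel optical attenuation over the neck; the mean attenuation over the
vessel region — jugular venous attenuation, JVA — rises with regional blood
volume because hemoglobin is the dominant time-varying absorber at 940 nm.
The catch is that the absolute attenuation also depends on hemoglobin
concentration, on the myoglobin-rich sternocleidomastoid muscle overlying the
vessel, and on vessel depth, all of which differ systematically between men
and women. `chitrack` implements a fully synthetic version of this
measurement problem: a generative tissue/camera model with known ground
truth, the complete camera-side extraction chain, a simulated ultrasound arm,
and the statistical battery that compares the two modalities across sexes and
fluid-shift levels.

Because every input is synthetic, every claim the package makes is a claim
about the generator, not about human data: what the tests demonstrate is that
the extraction chain and the statistics recover the structure the generator
put in, under realistic parameter values and noise.

## Cohort generator

`make_cohort()` samples one parameter set per participant from independent
truncated normals (3 sd, positive floor) around per-sex reference means
(`table1_parameters()`): supine CSA (women 0.60 ± 0.18, men 0.44 ±
0.25 cm²), sternocleidomastoid thickness (0.81 ± 0.14 vs 1.13 ± 0.23 cm),
depth to the IJV (1.17 ± 0.12 vs 1.51 ± 0.21 cm), and a relative hemoglobin
scale with the male mean 15% above the female mean — the accepted adult sex
difference. Field-to-field covariance is not modelled: the reference data
report only marginal means and SDs, and independent truncated normals are the
simplest defensible generative model. Whether the reference SDs reflect
between-person spread or include measurement error is not stated; we treat
them as between-person spread.

Two parameters are *not* reducible to anatomy:

* `jva_gain` — the participant's attenuation-per-area slope (a.u./cm²). The
  4–5× male/female ratio of individual JVA-vs-CSA slopes cannot be derived
  from hemoglobin and depth alone, so the slope is an explicit per-participant
  parameter, lognormal around per-sex medians of 0.23 (men) and 0.05 (women)
  a.u./cm², with log-sd (0.85 / 0.73) matched to the reported interquartile
  ranges. The optics then modulate it further (below), so hemoglobin and
  depth remain live confounds rather than being baked in.
* `hdt_delta` — the participant's CSA increase at −6° HDT, truncated normal
  0.19 ± 0.08 cm² (floor 0.02). Group-mean HDT responses of 0.15–0.23 cm²
  are repeatedly reported; the spread is what makes some participants
  "small-responders" whose CSA change stays under 0.15 cm², which the
  reliability analysis needs.

Heart rate (60–80 bpm) and respiratory rate (12–16 /min) are uniform; they
are not reported for the reference cohort and only set time scales.

`true_csa()` is deterministic: HDT interpolates linearly from baseline to
baseline + `hdt_delta`; LBNP removes 75% of the distance from baseline to a
0.05 cm² collapse floor by −40 mmHg, so smaller (typically male) veins
approach the floor first — the floor effect behind the loss of sex separation
at the deepest suction level. `render_dynamics()` superimposes the cardiac
venous pulse (anti-phase to the arterial PPG, amplitude 5% of mean CSA) and a
respiratory sinusoid (3%). The dynamics seed depends on the participant, not
the trial: one heart per person, so noise-free responses are exactly monotone
across levels.

Randomization follows the protocol: HDT and LBNP blocks in random order per
participant, levels inside each block in fixed sequence (0, −3, −6°;
0, −20, −30, −40 mmHg). One master seed derives labelled substreams
(participant parameters, schedule, dynamics, per-trial noise), so any single
trial is reproducible in isolation.

## Optical scene and camera model

`build_scene()` lays out a 64 × 64 px lateral neck view at 0.05 cm/px
(a deliberately desk-scale stand-in for a megapixel sensor): row 1 is
superior, the midline sits at row 24, the vessel runs along rows 33–56 —
strictly inferior to the midline — at a fixed column, a 2-px carotid strip
runs parallel, and an 8 × 8 px flexible reflectance target (reflectance
0.95, aligned to the 4 × 4 down-sampling grid) occupies the superior corner.

Attenuation follows a layered Beer–Lambert model in reflection mode:

$$A(x,y) = \mu_b\, h\, L_b(x,y;\mathrm{CSA})\, e^{-d/\delta} +
           2\,\mu_m\, T_{scm} + A_0,$$

with `h` the hemoglobin scale, `L_b` the two-pass path through the lumen,
`d` the vessel depth with sensitivity length δ = 1 cm (any monotone-decreasing
kernel would do; the exponential is the simplest), `T_scm` the muscle
thickness and `A_0` a static background. Two modelling choices matter:

* **Vessel geometry.** Distension is modelled as an ellipse of fixed lateral
  half-width and CSA-proportional anteroposterior height: compliant veins
  flatten and re-round rather than widen. Consequently the lateral footprint
  is constant across levels and the footprint-mean blood attenuation is
  *exactly linear* in CSA — which is what makes noise-free peak JVA strictly
  monotone across levels, mirroring the main effects of both challenges.
* **Effective absorptivities.** No optical constants are reported for the
  reference system, so `mu_myo` (0.056 /cm) and the background (0.383 a.u.)
  are solved once so that the median participant's baseline peak JVA lands at
  the reference anchors of 0.51 (women) and 0.61 (men) a.u. — the ~19% male
  excess that motivates sex-specific interpretation. Because `jva_gain` is
  right-skewed, cohort *means* of simulated JVA sit slightly above these
  median anchors. The per-participant `mu_blood` is solved so the realized
  slope equals `jva_gain` at reference hemoglobin (1.075) and depth
  (1.34 cm); the participant's own hemoglobin and depth then scale it through
  the forward model, keeping both confounds executable (JVA rises with
  hemoglobin, falls with depth, at fixed geometry).

`render_stack()` produces `I = I₀ · 10^(−A) + noise` at 30 s × 60 fps
(a fast 10 s × 30 fps mode is used for large test loops). Noise is
signal-dependent shot noise (variance ∝ intensity, scale 0.01) plus additive
read noise (sd 1 count on I₀ = 1000), both configurable; the target region
can be rendered noise-free for calibration oracles. Not modelled: photon
transport, cross-polarization, specular reflections, skin-tone/melanin
variation, motion between conditions — so the synthetic benchmark says
nothing about motion robustness or pigmentation bias in real recordings.

## Camera-side extraction (CHI chain)

`chi_extract()` fixes the order down-sample → calibrate → denoise →
correlate (the reference description implies but does not state the
calibrate/denoise order):

1. **4 × 4 mean down-sampling** (`downsample_4x4()`), exact block means,
   trailing partial blocks dropped — a 4× noise reduction.
2. **Calibration** (`calibrate_attenuation()`): per frame,
   `I₀ = mean(I[target]) / R_ref`, then `A = −log10(I/I₀)`; non-positive
   intensities become NA and invalidate their pixel.
3. **Temporal denoising** (`kalman_denoise()`): a per-pixel scalar
   local-level Kalman filter (process variance 1e-5, measurement variance
   1e-4). The reference system cites a "hemodynamic Kalman filter" whose
   internals live in prior work; the local-level filter is our documented
   stand-in with the same role — variance reduction without
   phase-destroying operations beyond the filter lag.
4. **Anticorrelation mapping** (`correlation_map()`): Pearson correlation of
   each pixel's attenuation series against the finger PPG, band-passed to
   the cardiac band (0.7–3 Hz, an addition that suppresses respiratory
   leakage into the correlation). Venous pixels anticorrelate; arterial
   pixels correlate positively.
5. **ROI localization** (`localize_ijv()`): threshold r < −0.3 (unstated in
   the reference; configurable and swept in tests), restrict to rows below
   the midline, 8-connected components (robust to thin down-sampled
   vessels; 4-connectivity available), keep the largest, break ties toward
   the smallest row-major top-left coordinate, and cap the extent along the
   vessel axis at ceil(1 cm / 0.2 cm) = 5 px centred on the component
   centroid — the "~1 cm segment" constraint. No qualifying pixel yields an
   explicit no-ROI signal and the trial is dropped, mirroring the excluded
   acquisitions in the protocol this emulates.
6. **JVA extraction** (`extract_jva()`): the per-frame ROI mean, with the
   acquisition peak as the analysis value (suppressing respiratory
   variability). Whether the reference peak is taken on a raw or smoothed
   series is unstated; a smoothing window is exposed and defaults to off.

## Simulated ultrasound

`make_cineloop()` produces 5 s of ground-truth CSA at 23 fps from the same
dynamics model (same heart as the camera trial).
`select_post_rspike_frames()` picks, for each ECG R-spike, the first frame
strictly after the spike (frame `floor(s·fps) + 2` in 1-based indexing) —
approximately the venous c-wave. `measure_csa()` replaces ellipse tracing on
B-mode speckle with ground truth plus truncated Gaussian operator noise
(sd 0.02 cm², configurable; no value is reported for the reference) and
takes the maximum across the ~5 cardiac cycles. Left/right vessel asymmetry
(ultrasound on one side, camera on the other) is not modelled; both arms read
the same ground-truth vessel.

## Statistics

* `rmcorr()` — repeated-measures correlation via the ANCOVA decomposition:
  participant-intercept model with one common slope,
  `r_rm = sign(slope)·sqrt(SS_x/(SS_x + SS_err))`, df = N(k−1)−1, F test on
  the covariate, Fisher-z CI with the repeated-measures df. It is verified
  against an explicit dummy-coded least-squares oracle to 1e-10.
* `fit_lmm()` — `response ~ sex * level + (1 | participant)` by REML with
  Satterthwaite fixed-effect tests, optionally adjusted for baseline (0°)
  CSA; post hoc Tukey-adjusted pairwise EMM contrasts over the sex-by-level
  cells, from which the per-level sex differences are extracted.
* `individual_fits()` / `summarise_fits()` — per-participant OLS with
  median/IQR summaries (type-7 quantiles; no quantile rule is stated in the
  reference). Negative individual slopes are retained in summaries.
* `compare_slopes()` — two-sided Wilcoxon rank sum, exact for combined
  n ≤ 20 without ties, otherwise normal approximation with tie and
  continuity correction.
* `stratify_reliability()` — IQR of individual r above/below a 0.15 cm² CSA
  change, pooled across conditions and sexes.
* `anthropometric_correlations()`, `demographics_tests()` — pooled Pearson
  correlations of baseline JVA with muscle thickness and vessel depth, and
  Student's t demographics table.

The analytic trial-table generator (`simulate_trial_table()`) is the
closed form of the rendered pipeline (realized slope × peak vessel state +
muscle + background, plus measurement noise: 0.02 cm² ultrasound, 0.003 a.u.
JVA) and exists so that hundred-cohort statistical simulations do not require
hundred-fold video rendering; agreement of the two paths is covered by the
round-trip and monotonicity tests of the rendered chain.

## Problem sizes and numerical choices

Default experiments use 10 men + 10 women with the analysed-cohort dropout
structure (one woman fully excluded, one man's LBNP block excluded; 9 women
overall, 9 men for LBNP). Rendered test loops use the 10 s × 30 fps fast
mode and 64 × 64 scenes; unit tests use a 16 × 16 fixture scene. Simulation
studies use 100–200 seeded cohorts via the analytic generator. These sizes
were chosen so the full suite runs comfortably on a laptop-class single
core while keeping every Monte-Carlo margin interpretable.

Degenerate inputs are handled explicitly: constant covariates exclude a
participant from rmcorr (warning) and from individual fits; empty reliability
strata are flagged, not fatal; non-positive intensities are masked during
calibration; a missing venous ROI drops the trial. Ties in component size
break deterministically (row-major top-left). The PPG beat assignment guards
sample-on-onset boundaries with a 1 ns epsilon.

## Known limitations

* The optical model is effective, not radiative-transfer-accurate; absolute
  attenuation values are anchored, not derived.
* The reliability phenomenon (unstable individual correlations below
  0.15 cm² CSA change) is reproduced in expectation — the low-change stratum's
  IQR of individual r is several times wider on average — but the per-cohort
  ordering holds in roughly 85–95% of cohorts, not ≥95%: the low stratum holds
  only a handful of fits, and a single iid noise level cannot make moderate
  responders as unreliable as contralateral measurement made them in practice.
* Measurement-error correlation between the two arms is absent (independent
  noise draws), which slightly flatters the repeated-measures correlations
  relative to contralateral measurement in practice.
* Nothing here validates performance on real video: motion, pigmentation,
  ambient light and probe pressure are all outside the generator.
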