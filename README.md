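# chitrack

Synthetic coded hemodynamic imaging (CHI) of the internal jugular vein:
a generative optical model, the camera-side extraction chain, a simulated
ultrasound arm, and the statistical comparison of the two modalities across
fluid-shift challenges in men and women.

## What problem this addresses

Jugular venous attenuation (JVA) — the mean near-infrared optical
attenuation over the internal jugular vein, measured without contact by a
camera — is a promising proxy for central venous volume: the vessel distends
under head-down tilt (HDT: 0, −3, −6°) and empties under lower-body negative
pressure (LBNP: 0, −20, −30, −40 mmHg). But absolute attenuation also
reflects hemoglobin concentration, overlying sternocleidomastoid muscle and
vessel depth, all sex-dependent, so JVA must be interpreted against the
ultrasound reference (cross-sectional area, CSA) in a sex-aware way.

`chitrack` builds this measurement problem end to end *in silico*, with known
ground truth, for anyone developing or stress-testing camera-based venous
monitoring pipelines:

* **Cohort generator** — per-sex anatomy/physiology (CSA, muscle thickness,
  vessel depth, relative hemoglobin with the ~15% male excess), a
  participant-specific attenuation-vs-area slope, deterministic per-level
  vessel responses, randomized condition blocks.
* **Optics** — layered Beer–Lambert rendering
  `I = I₀ · 10^(−A)`, with
  `A = μ_b h L_b(CSA) e^{−d/δ} + 2 μ_m T_scm + A₀`,
  a flexible reflectance target for calibration, a carotid strip pulsing in
  phase with the finger PPG, shot + read noise.
* **CHI chain** — 4×4 mean down-sampling, reflectance-target calibration to
  attenuation, per-pixel local-level Kalman denoising, PPG anticorrelation
  mapping, largest-contiguous-region vessel localization inferior to the
  neck midline, peak-JVA extraction.
* **Ultrasound arm** — 5-s 23-fps cine loops, post-R-spike frame selection,
  maximum CSA across ~5 cardiac cycles with operator noise.
* **Statistics** — repeated-measures correlation (ANCOVA common slope:
  `r_rm = sign(b)·√(SS_x/(SS_x+SS_err))`, df = N(k−1)−1), linear mixed
  models `response ~ sex × level + (1|participant)` with Satterthwaite tests
  and Tukey-adjusted per-level sex contrasts, per-participant regressions
  with median/IQR summaries, Wilcoxon slope comparison, and reliability
  stratification of individual correlations at a 0.15 cm² CSA change.

## Worked example

The `analysis/` scripts run the whole study as a narrative sequence:

```sh
Rscript analysis/01_simulate.R            # cohort + rendered trials -> results/
Rscript analysis/02_mixed_models.R        # group-level mixed models
Rscript analysis/03_jva_csa_association.R # JVA-vs-CSA association
```

Stage 1 (reduced 10-s acquisitions; `--full` renders 30 s at 60 fps) prints:

```
analysed cohort: 9 women, 10 men; 129 trials
baseline JVA: women 0.52, men 0.59 a.u. (men +15%)
baseline CSA: women 0.82, men 0.52 cm2
ROI localization IoU vs ground truth: median 0.83 (min 0.04)
```

i.e. after the built-in exclusions (one woman and one man's LBNP block)
129 trials remain; men show
the higher baseline attenuation despite the smaller vessel, and the
localized region overlaps the ground-truth vessel footprint with median
IoU 0.83. Stage 2 then reports, per condition and response, e.g.:

```
== JVA during HDT ==
level p = 5.67e-06, sex p = 0.0039, sex x level p = 0.00125
== CSA during LBNP ==
level p = 2.14e-22, sex p = 0.00302, sex x level p = 4.07e-06
```

— attenuation rises with tilt and is higher in men with a steeper male
response, while women have the larger (and faster-shrinking) CSA under
suction. Stage 3 quantifies agreement between the modalities:

```
== LBNP ==
  men  : r_rm = 0.70 (95% CI 0.44, 0.85), p = 3.77e-05, common slope = 0.127 a.u./cm2
  women: r_rm = 0.89 (95% CI 0.78, 0.95), p = 1.61e-10, common slope = 0.044 a.u./cm2
  male vs female slopes: W = 72, p = 0.00399 (exact)

== Reliability of individual correlations by CSA change ==
 stratum  n r_q25 r_q75 iqr_width  flag
     low  7 0.915  0.99   0.07529 FALSE
    high 30 0.992  1.00   0.00798 FALSE
```

— strong common-slope correlations with a several-fold steeper male slope,
and individual-level correlations that become markedly more variable when a
participant's CSA changes by less than 0.15 cm².

All numbers above are what the scripts printed for master seed 20260928;
they move within sampling error for other seeds. The methods vignette
(`vignettes/chitrack-methods.Rmd`) documents the generative model, every
tunable parameter and the design decisions.

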