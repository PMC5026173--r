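# xeventmap

Quantitative analysis of hyperpolarized (hp) xenon-129 ventilation MRI
under bronchoconstrictive challenge.

## The problem

Hp ¹²⁹Xe MRI images inhaled gas directly: signal intensity maps regional
gas delivery in the lung. When a lung is challenged with increasing
intravenous doses of methacholine (MCh), bronchoconstriction reduces and
redistributes that delivery — earlier, more strongly and far more
heterogeneously in allergic-asthma (ovalbumin, OVA) phenotypes than in
healthy controls. `xeventmap` is for researchers analyzing such
baseline-plus-dose challenge image series (or developing methods for
them): it implements the full analysis chain and a digital lung phantom
simulator so every stage is testable without scanner data.

For a challenge image $M$ and baseline $B$ on a grid of $k$ voxels the
core quantities are

* the **normalized global signal intensity**
  $\mathrm{GS} = \sum_i M_i / \sum_i B_i$ (whole-lung dose-response
  readout),
* the **absolute intensity difference map** $\Delta A_i = M_i - B_i$,
* the **relative intensity difference map**
  $\Delta R_i = \left(\frac{M_i}{k^{-1}\sum M} - \frac{B_i}{k^{-1}\sum B}\right)\cdot\frac{100\%}{\mathrm{GS}}$,
  which isolates gas *redistribution* from global loss, and
* $\sigma_\mathrm{RID}$, the standard deviation of $\Delta R$ over the
  lung — a scalar index of regional ventilation heterogeneity.

Around these sit sine-bell-squared apodized Fourier reconstruction of
raw k-space, background-ROI (mean + 3 SD) lung segmentation and SNR
estimation, background-noise consistency monitoring (< 20% fluctuation),
Bland-Altman method agreement, and dose-response group comparison by
two-way ANOVA with Bonferroni-corrected per-dose contrasts. The
simulator provides two-lobed lung phantoms with per-region Hill-sigmoid
dose responses, a constant-signal variable-flip-angle FLASH acquisition
model and complex k-space noise (Rician magnitude background).

## Worked example

Simulate an OVA-phenotype challenge series (two baselines, the standard
10/25/50/75/100/200/400 µg MCh schedule, a reversal frame) and run the
full pipeline:

```r
library(xeventmap)

spec <- ova_phantom_spec(seed = 11)
res <- run_pipeline(run_config(spec = spec, reversal = TRUE,
                               seed = 11, roi_seed = 11))
res$metrics[, c("label", "cumulative_dose_ug", "gs", "snr",
                "mean_difference", "sigma_RID")]
```

```
       label cumulative_dose_ug    gs  snr mean_difference sigma_RID
1  baseline1                  0 1.000 51.5              NA        NA
2  baseline2                  0 0.999 58.7              NA        NA
3   mch_10ug                 10 0.976 52.5         -0.0155      10.5
4   mch_35ug                 35 0.883 45.5         -0.0769      21.5
5   mch_85ug                 85 0.720 39.8         -0.1818      46.5
6  mch_160ug                160 0.592 29.2         -0.2693      71.7
7  mch_260ug                260 0.509 29.1         -0.3189      90.8
8  mch_460ug                460 0.447 22.8         -0.3647     106.2
9  mch_860ug                860 0.413 20.6         -0.3864     109.1
10  reversal                860 0.705 38.5          0.1929      20.1
```

Reading the table: baseline whole-lung SNR is ~50–59, as expected for an
inflamed lung at this noise level. GS falls steeply over the first
doses (0.98 → 0.59 by 160 µg cumulative) and reaches 0.41 at the 860 µg
maximum — a 59% loss of inhaled gas signal — while `mean_difference`
(mean ΔA over the lung) grows correspondingly negative.
`sigma_RID` rises from ~10% (noise floor) to ~109%, showing strong
regional heterogeneity of the response. The reversal frame, referenced
against the 860 µg image, has a *positive* mean difference: the
bronchodilator restored part of the gas volume. A control-preset run
(`control_phantom_spec()`) stays near GS ≈ 0.8 with σ_RID an order of
magnitude smaller.

With `out_dir` set, the pipeline writes per-frame NIfTI images and
masks, ΔA/ΔR maps (NIfTI + diverging-colormap PNG), `metrics.csv`,
`gs_curve.csv`, `noise.csv` and a YAML manifest that makes the run
exactly reproducible.

Group comparison of simulated cohorts:

```r
cmp <- compare_dose_response(gs_table)  # columns: subject, group, dose, gs
cmp$anova       # group, dose, interaction
cmp$contrasts   # per-dose t, Bonferroni-adjusted p
```

## Documentation

The methods vignette (`vignettes/xeventmap-methods.Rmd`) documents the
signal model, the segmentation and windowing conventions, the phantom's
dose-response parameterization and calibration defaults, the statistical
procedures, and known limitations.
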