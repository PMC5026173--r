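---
title: "Quantifying bronchoconstriction with hyperpolarized-gas ventilation MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bronchoconstriction with hyperpolarized-gas ventilation MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xeventmap)
```

# The measurement problem

Hyperpolarized (hp) xenon-129 is an inhaled MRI contrast gas: its
nonequilibrium polarization gives bright signal wherever gas reaches the
airspaces, so a 2D projection image of an inflated lung is, to a good
approximation, a map of regional gas delivery. Under a cumulative
intravenous methacholine (MCh) challenge, bronchoconstriction reduces and
redistributes that delivery. In the allergic-asthma (ovalbumin, OVA)
phenotype the response sets in at much lower doses and is regionally far
more heterogeneous than in healthy lungs.

`xeventmap` implements the analysis chain for such challenge series —
reconstruction, segmentation, global and regional change metrics, and
group statistics — together with a digital lung phantom and acquisition
simulator, so that every stage can be exercised and validated without
access to scanner data.

# Signal model and metrics

For a challenge image $M$ and baseline image $B$ on the same grid of $k$
voxels:

* **Normalized global signal intensity.**
  $\mathrm{GS} = \sum_i M_i \big/ \sum_i B_i$, by default over all $k$
  voxels of the image. A curve of GS against cumulative dose is the
  whole-lung dose-response readout. `global_signal_curve()` also supports
  an *averaged reference* (the mean voxel-sum of the baseline frames, any
  fluid frame, and the lowest-dose frame), which compensates shot-to-shot
  polarization fluctuations when, as here, every image comes from an
  independent hp-gas batch.
* **Absolute intensity difference.** $\Delta A_i = M_i - B_i$, in signal
  units. Sensitive to any loss of gas delivery, but at strong global
  constriction the global loss dominates and hides redistribution.
* **Relative intensity difference.**
  $\Delta R_i = \left( \frac{M_i}{k^{-1}\sum M} - \frac{B_i}{k^{-1}\sum B} \right) \cdot \frac{100\%}{\mathrm{GS}}$.
  Each image is first reduced to voxel *shares* of its own total, so
  $\Delta R$ isolates redistribution; the $1/\mathrm{GS}$ scaling
  re-expresses the share change relative to the constricted total.
  Values below $-100\%$ are legitimate (baseline voxels can hold more
  than the mean share). By construction the mean of $\Delta R$ over the
  full domain is exactly zero — a property the tests assert to
  $10^{-10}$.
* **Heterogeneity index.** $\sigma_\mathrm{RID}$, the standard deviation
  of $\Delta R$ over the analysis mask. We use the population
  ($n$-divisor) SD: the map is a complete enumeration of the masked
  voxels, not a sample from a larger population, so the descriptive
  divisor is the appropriate one.
* **Reversal convention.** A bronchodilator-reversal frame is compared
  against the *final-dose* frame (maximum cumulative dose), not the
  baseline, so its difference maps show what the reversal restored.

The default analysis mask for the map summaries is the union of the
baseline and current lung masks: background voxels carry only noise and
would dilute $\sigma_\mathrm{RID}$ toward the Rician floor. Both the
whole-image and masked domains are exposed, since either choice is
defensible for the global metrics.

# Reconstruction

Raw data are complex 2D k-space matrices (128 × 64 read × phase by
default, FOV 47.3 × 31.5 mm, in-plane voxel 0.37 × 0.49 mm). Before the
2D inverse DFT a separable sine-bell squared window is applied,

$$w[n] = \sin^2\!\left(\pi \frac{n + 1/2}{N}\right), \qquad n = 0, \dots, N-1,$$

sample-centered so that no edge sample is exactly zeroed and the window
is symmetric about the matrix center. K-space is stored DC-centered and
half-swapped around the transform, so images are never quadrant-swapped.
Magnitude (not real-part) images are analyzed. No zero-filling is
applied. The window trades resolution for noise and ringing suppression;
the tests verify Parseval's identity without the window and the
point-spread broadening with it.

# Segmentation and SNR

The lung mask is obtained by thresholding at the **background ROI mean
plus three standard deviations**, with the ROI a 10 × 10 voxel block
placed randomly (seeded) in the background. Design choices:

* *ROI placement.* The provisional foreground is estimated with Otsu's
  bimodal threshold, and candidate ROI positions must be clear of it by a
  5-voxel margin ("far removed from the lung"). A fixed percentile cut
  was considered and rejected: with the lung occupying ~37% of the grid,
  a 75th-percentile cut falls inside the lung intensity range and lets
  the ROI straddle dim lung tissue; without the margin, point-spread
  tails beside the lung inflate the noise SD estimate severalfold.
* *Boundary rule.* The threshold comparison is inclusive (≥), for
  deterministic behaviour at ties.
* *SNR estimator.* Whole-lung SNR = mean in-mask signal / background SD.
  No Rician bias correction is applied to the background SD — a known
  limitation, accepted for fidelity to common practice; the bias is a
  fixed factor at zero signal and cancels in relative comparisons.
* *Noise-consistency monitor.* Per-frame background means are compared to
  the first frame; a fluctuation of ≥ 20% is flagged (a warning, or an
  error under `strict`). The pipeline reuses one ROI *position* across
  the frames of a series, so the monitor sees the noise level rather
  than placement variability. Note the estimator itself is noisy: a
  100-voxel ROI mean has ≈ 5% sampling error, so the max-over-frames
  statistic occasionally exceeds 20% even at perfectly constant noise.

In the strict noise-free limit the 3·SD rule degenerates (the threshold
collapses toward zero and the mask annexes the full point-spread skirt);
at realistic SNR the threshold sits at a few percent of the lung signal
and the mask is the true lung plus a 1–2 voxel halo. The tests assert
exactly that: no lung voxel missed, stray voxels confined to a 2-voxel
boundary band, Dice ≥ 0.90 against ground truth.

# The phantom and acquisition simulator

`make_phantom()` builds a two-lobed coronal lung template (two ellipses,
the anatomical left slightly smaller, ~37% grid occupancy at any grid
size), partitioned into contiguous regions by a seeded Voronoi rule.
Each region follows a Hill sigmoid response to cumulative dose $D$:

$$v_r(D) = 1 - E_{\max,r} \frac{D^{h}}{D^{h} + EC_{50,r}^{h}},$$

the standard minimal pharmacological model for a graded agonist
response; the source experiments report only qualitative dose behaviour,
so the sigmoid is a modelling choice, not a fitted form. Regional
heterogeneity is a single dial $\eta$: $\log EC_{50}$ spread
$0.5\eta$, $E_{\max}$ spread $0.15\eta$ (clipped to $[0,1]$), log-Hill
spread $0.1\eta$. $\eta = 0$ collapses all regions onto identical
parameters.

Phenotype presets (calibration defaults, not ground truth):

| preset | $EC_{50}$ (µg) | $E_{\max}$ | $\eta$ | amplitude |
|---|---|---|---|---|
| control | 500 | 0.3 | 0.3 | 1.00 |
| OVA | 120 | 0.7 | 1.0 | 0.72 |

These were chosen once so that simulated GS curves bracket the observed
phenotype contrast — a near-flat control and a > 50% global-signal loss
for OVA at the 860 µg maximum cumulative dose — and so the baseline
whole-lung SNR lands near 70 (control) and 50 (OVA) at the shared
k-space noise level (`noise_sd = 4.5` per complex channel, calibrated
once against those stated SNR ranges with the default windowed
reconstruction).

The acquisition forward model is the 2D DFT of the amplitude map, each
phase-encode line scaled by the flip-schedule transverse-signal factor,
plus independent complex Gaussian k-space noise — so the reconstructed
magnitude background is Rician, as in real scanner data (mean/SD ratio
$\sqrt{\pi/2}/\sqrt{2-\pi/2} \approx 1.91$ at zero signal, verified by
Monte-Carlo). Hyperpolarized magnetization is nonrenewable, so the
variable flip angle (VFA) schedule

$$\theta_j = \arctan\frac{1}{\sqrt{n-j}}, \qquad j = 1, \dots, n$$

is used; it yields exactly $1/\sqrt{n}$ of the initial magnetization on
every line (machine-precision constant, asserted to $10^{-10}$). Slice
selection is carried as a labelled acquisition mode only — no RF slice
profile, diffusion attenuation or T1 physics is modelled. Inhaled-volume
or airway-pressure mechanics are likewise not modelled: the reported
pressure ranges have no stated mapping to image amplitude, so dose acts
directly on the regional response.

What the simulator deliberately does **not** emulate about real data:
anatomical texture beyond a mild apical-basal gradient and per-region
amplitude variation; airway structures; motion or inflation-level
differences between frames (the real protocol acquired each image on a
separate inhalation, and registration was not part of the analysis —
the pipeline warns rather than registers); polarization drift between
batches (frames are independently noised at a constant level). Passing
tests therefore validate the *analysis chain* — reconstruction algebra,
thresholding behaviour, metric definitions, statistical machinery —
not the biological realism of any particular parameter value.

# Statistics

* **Bland-Altman** (`bland_altman()`): bias = mean paired difference,
  95% limits of agreement at the conventional 1.96 multiplier (no
  multiplier is stated in the source convention; 1.96 is the standard
  choice), on either the raw or the percent-of-pair-mean scale.
* **Dose-response comparison** (`compare_dose_response()`): two-way
  ANOVA of GS with factors group and dose plus interaction. Balanced
  designs use the sequential decomposition (whose sums of squares
  partition the total exactly — asserted in the tests); unbalanced
  designs fall back to type II sums of squares. Per-dose group contrasts
  are Student's t tests with Bonferroni correction (raw p × number of
  dose levels, capped at 1, α = 0.05). The family-wise type-I error of
  this procedure is verified ≤ 5% by a 500-replicate simulated null.
* **t tests** (`two_sample_t()`): Student's flavor by default, Welch by
  flag. The fully degenerate zero-variance case is resolved by
  convention (equal means → p = 1; unequal → p = 0).

# Numerical and interface choices

* Even matrix dimensions are required for acquisition (the DC-centering
  half-swap is then self-inverse); phantom grids only need ≥ 8 voxels
  per axis and ≥ 1 voxel per requested region.
* Voxels `NA` in either frame of a pair are excluded from all sums,
  means and masks, and the exclusion count is reported.
* All randomness is seeded: phantom construction from the spec seed,
  per-frame noise from seeds derived deterministically from one master
  seed, ROI placement from its own seed. Identical configuration gives
  byte-identical CSV outputs, which the tests assert.
* K-space persistence uses RDS; images, masks and difference maps are
  written as NIfTI (voxel dimensions from FOV/matrix), rendered maps as
  PNG (blue/red diverging scale for ΔA, magenta/green for ΔR), tables
  as CSV, and the run manifest (configuration, seeds, package version)
  as YAML. The pipeline interface is the function surface
  `run_config()` + `run_pipeline()`.

# Problem sizes used in validation

The test-suite simulations run at the native 128 × 64 acquisition
geometry. Monte-Carlo checks use 20–50 noise seeds (Rician and
threshold-tail statistics), 10 seeds × 5 heterogeneity levels for the
$\sigma_\mathrm{RID}$ monotonicity sweep, 10 simulated subjects per
phenotype for the preset-ordering checks, and 500 replicates for the
family-wise error simulation. These sizes were chosen to keep
Monte-Carlo error comfortably inside the asserted margins.

# Known limitations

* 2D projection only; no 3D acquisition, partial-Fourier, regridding or
  non-Cartesian trajectories.
* No gas-exchange/dissolved-phase modelling, no fractional-ventilation
  analysis (single breath-hold model).
* No inter-frame registration; metrics assume a stationary lung between
  frames.
* The Rician noise floor biases background statistics (no correction
  applied, by design), and $\sigma_\mathrm{RID}$ has a noise floor that
  grows as GS falls — comparisons between phenotypes should be made at
  matched dose and noise, as the pipeline does.
* The phantom's heterogeneity ratio between presets is a calibration
  choice; simulated $\sigma_\mathrm{RID}$ ratios depend strongly on it
  and on the GS scaling, and should not be read as predictions of any
  particular measured ratio.
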