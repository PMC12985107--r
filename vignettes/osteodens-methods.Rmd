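---
title: "Methods: CT-based cancellous bone quality of the humeral head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT-based cancellous bone quality of the humeral head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`osteodens` implements three CT-based readouts of cancellous bone quality
in the proximal humeral head and the statistics needed to compare them
within specimens and across imaging modalities:

1. **ROI-mean attenuation index** ("CT-OAM-inspired"): an 8-bit ROI mean
   on maximum-intensity projections, scaled by the modality display
   window. A relative index in arbitrary units, not an absolute density.
2. **Phantom-calibrated cancellous vBMD** (Krappinger-style): HU means in
   three equidistant axial ROIs, water-equivalent correction, linear
   phantom calibration to mg/cm³.
3. **Segmentation-based trabecular density** (BMA-style): threshold
   segmentation of cortical and trabecular compartments with
   modality-specific lower bounds, morphological map refinement, and the
   calibrated trabecular mask mean.

Because real cadaveric scans of this kind are not publicly available, the
package ships a synthetic-cohort generator with exact voxel-level ground
truth, so that every stage — preprocessing, segmentation, ROI placement,
calibration, statistics — can be validated end to end.

## The synthetic phantom model

A specimen is a sphere (default radius 22 mm) carrying a dense cortical
shell (default 1.5 mm, density 1100 mg/cm³) and truncated distally at the
surgical-neck landmark (default 85 % of the axial extent). These
dimensions are fabricated but plausible for an adult humeral head; no
measured specimen geometry stands behind them, and they are parameters,
not constants.

The trabecular interior carries the specimen's ground-truth mean density
$D$ modulated by three zero-mean fields:

* a **radial densification gradient** (default +10 % center to
  periphery): real humeral heads are denser subchondrally than centrally;
  the gradient is deterministic and identical in shape across specimens;
* a **sinusoidal trabecular lattice** (default amplitude 0.25, period
  1.6 mm): the simplest stand-in for the quasi-periodic plate/rod
  structure of trabecular bone. Its phase is fixed, so like the gradient
  it is a common structural template across specimens. Its practical role
  is to give every ROI an intensity spread of at least about two 8-bit
  display bins, which makes the quantized ROI mean a strictly increasing
  function of density instead of a staircase with flat spots;
* a **stochastic texture** (Gaussian-smoothed white noise, correlation
  length 1.5 mm, default contrast 0.2), the per-specimen random
  component, plus optional additive Gaussian intensity noise.

All three modulations are re-centered to zero mean over the trabecular
mask, so the realized interior mean density equals $D$ exactly — the
recorded ground truth is exact by construction, not approximate.

"**Noiseless**" conditions in the test suite mean `noise_sd = 0` *and*
`texture_contrast = 0`: the texture is smoothed white noise and is
therefore treated as a noise term, while the gradient and lattice are
deterministic structure and stay on. Under noiseless conditions every
method output is a common, strictly monotone function of $D$, which is
why identical specimen rank order across all five method/modality series
is an analytic property rather than a sampling accident. With texture on,
slice-sampled methods acquire small specimen-specific perturbations and
exact rank identity is no longer guaranteed — this mirrors real data, and
it is why the rank-preservation checks specify noiseless cohorts.

### Rendering

A render model maps density to intensity affinely
(`intensity = slope * density + intercept`) on an isotropic grid, with an
optional Gaussian point-spread blur (default off). Defaults: clinical CT
0.5 mm voxels, slope 0.32, intercept 195; micro-CT 0.2 mm voxels, slope
1.1, intercept 200. The micro-CT render is generated directly at 0.2 mm —
the working resolution of the analysis after resampling — rather than at
a finer native grid, to keep volumes desk-scale. The slopes and
intercepts are chosen so that trabecular intensities of a cohort within
±3 SD of the default density model (mean 150, donor SD 30, residual SD 5
mg/cm³) stay strictly inside the fixed segmentation bands (200–300 for
clinical CT, 200–600 for micro-CT), while the cortical shell lies above
the cortical bound in both modalities. What the generator deliberately
does **not** emulate: anatomical head shape, beam hardening, scatter,
metal artifacts, and the physics of the scanner — passing tests show that
the *algorithms* are correct, not that the method is robust to those
physical effects.

Each specimen is rendered at both modalities from the same continuous
density field: texture sub-seeds hash (donor, side) only, never the
modality, while the additive noise sub-seed does include the modality.
Sub-seeds are derived from the global seed by a stable string hash, so
results do not depend on generation order.

### Cohort model

Specimen densities follow the donor-clustered model
$D_{ij} = \mu + b_i + e_{ij}$ with $b_i \sim N(0, \sigma_b^2)$,
$e_{ij} \sim N(0, \sigma_e^2)$, two sides per donor. Defaults
$\mu = 150$, $\sigma_b = 30$, $\sigma_e = 5$ give an intraclass
correlation of $900/925 \approx 0.973$ — strongly clustered, as bilateral
specimens are. Densities below a floor (10 mg/cm³) are redrawn (or the
run fails, per configuration).

## Pre-processing

Volumes are denoised with a 3×3×3 median filter (border policy:
replicate; the border rule is a documented choice, exposed as a
parameter), resampled to cubic voxels by trilinear interpolation when
anisotropic, and cropped axially from the first slice containing bone to
the surgical-neck landmark. Slice indices are 1-based and extents are
inclusive on both ends. The bone-presence threshold is not dictated by
any workflow; defaults are 150 (clinical CT) and 300 (micro-CT),
config-exposed. I/O is NIfTI; DICOM series should be converted upstream.

## The three workflows

### ROI-mean index

The head extent is divided into five equal bands and the centers of the
three middle bands are the measurement levels
(`first + round((k - 0.5) n / 5)`, `k = 2, 3, 4`, rounding half away from
zero — R's default round-half-to-even would make level placement depend
on parity, so the rule is fixed). At each level a MIP is taken over 2
slices (clinical CT) or 7 slices (micro-CT); an even slab extends
distally, a documented tie-break. The MIP is windowed to 8 bits over
0–1500 (clinical) or 0–3000 (micro-CT); a central disk ROI is placed at
the cancellous centroid with the largest in-mask radius minus a 2 px
margin; non-black pixels (8-bit value > 0) feed the descriptive
statistics, and

$$\mathrm{index} = \frac{\mathrm{mean}}{256} \times \mathrm{HU_{max}}.$$

The 256 denominator is kept verbatim as published even though the 8-bit
maximum is 255, so a saturated ROI attains $(255/256)\,\mathrm{HU_{max}}$,
not $\mathrm{HU_{max}}$. Quartiles interpolate linearly between order
statistics. The specimen index is the mean of the three level indices.

### Calibrated vBMD

Three axial ROIs sit at quarter fractions (¼, ½, ¾) of the head extent —
the anchor positions are a documented choice, config-exposed. Each ROI is
a disk at the cancellous centroid with diameter 85 % of the maximal
inscribed cancellous diameter (the reduction exists to exclude cortex, so
it applies to the inscribed cancellous diameter, not the outer head
diameter). HU values below the water-equivalent reference are **clamped**
to it — the simplest correction consistent with preventing fatty-marrow
negative bias; clamp-vs-exclude is an interpretation, and both the rule's
parameter (`water_hu`, default 0) and `-Inf` to disable it are exposed.
The specimen HU (mean of the three ROI means) converts to mg/cm³ via the
linear phantom calibration.

### Segmentation-based trabecular density

The "automatically determined" upper threshold is read as the volume
maximum — the least-assumption rule, overridable. Cortex is the largest
6-connected component at or above the cortical lower bound; the cortical
envelope is hole-filled **per axial slice** (2D, matching the slice-wise
manual editing the refinement replaces); trabecular voxels lie in
`[trabecular_min, cortical_min)` inside the envelope. Manual object-map
editing is replaced by deterministic morphology: per-slice closing of the
cortex (disc radius 2 px), largest-component reduction, per-slice opening
of the trabecular mask (disc radius 1) and removal of components below 5
voxels, with disjointness re-enforced (cortex wins ties). The trabecular
density is the calibrated mask mean; micro-CT values pass through an
identity calibration because that acquisition already stores calibrated
densities (mg HA/cm³) — which is also why micro-CT and clinical-CT
absolute values sit on systematically different scales and are never
compared directly.

## Calibration

Cylindrical inserts of known density are measured by their mask means and
density is regressed on intensity (OLS): density is the response because
the model's use is converting grayscale to BMD. The insert densities of
the synthetic phantom (0, 100, 200 mg/cm³) are arbitrary defaults — the
physical reference phantom's insert densities are not public. Fits are
exact on collinear points and equivariant under affine intensity
rescaling; parameter recovery under noise is part of the test suite.

## Statistics

* **Normality gates**: Shapiro–Wilk (base R implementation), on raw
  variables, paired differences, and regression residuals.
* **Paired comparison**: classical paired t with 95 % CI. Cohen's
  d uses the paired convention $d = \bar{d}/s_d = t/\sqrt{n}$ and
  Hedges' g the correction $J = 1 - 3/(4\,\mathrm{df} - 1)$ with
  $\mathrm{df} = n - 1$ — the unique pair of conventions consistent with
  the published triple (t = 19.24, d = 5.55, g = 5.17) reproduced in the
  acceptance tests.
* **Cross-modality agreement**: OLS with micro-CT as response, with R²,
  the overall F test, and the Durbin–Watson statistic on residuals in
  specimen order (donor, then side — the ordering is logged, since DW is
  order-dependent). An exact fit leaves DW undefined and flagged, never
  NaN.
* **Scale harmonization**: per-method z-standardization (sample SD,
  n−1). Mixed-unit comparisons without prior z-scoring are refused by the
  pipeline's unit guard.
* **Repeated-measures ANOVA**: one-way within-subject
  $F = MS_\mathrm{method}/MS_{\mathrm{method}\times\mathrm{subject}}$;
  Mauchly's W from the orthonormal-contrast covariance with the standard
  chi-square approximation; Greenhouse–Geisser
  $\varepsilon = \mathrm{tr}(A)^2 / ((k-1)\,\mathrm{tr}(A^2))$ from the
  same contrast covariance, deflating both degrees of freedom; corrected
  and uncorrected p are always reported together. On z-standardized
  columns every column mean is 0, so the method sum of squares — and
  hence F — is exactly 0 and p is exactly 1 for *any* complete,
  non-degenerate matrix: an analytic identity, not an empirical finding.
  Identical columns make both numerator and denominator zero; that case
  returns a degenerate flag instead of 0/0.
* **Donor clustering** is a property of the design and is reported
  (the generator's ICC), but no mixed model is fitted: comparisons are
  paired within specimens, mirroring the methodological rather than
  population-level aim.

## Pipeline

`run_pipeline()` chains cohort generation (or a supplied manifest),
calibration-phantom fitting, per-specimen preprocessing, the three
workflows per modality (the vBMD method is clinical-CT only; micro-CT
contributes the segmentation density and the ROI-mean index, 12 × 3 +
12 × 2 = 60 records for the default design), the unit guard, and the
statistics layer. Outputs (specimen CSV, descriptive/regression/paired/
ANOVA tables, JSON summary, plain-text log of every resolved parameter)
are staged in a temporary directory and moved into place only on success.
ROI placement on synthetic specimens uses the generator's ground-truth
cancellous masks — the analog of manual ROI placement on known anatomy;
on real data the segmentation-derived trabecular mask would take that
role.

## Problem sizes and runtime choices

Unit tests run on reduced phantoms (8 mm heads at 0.8/0.4 mm voxels);
the end-to-end acceptance checks use the full default geometry (22 mm
heads, 0.2 mm micro-CT grids, ~240³ voxels per micro-CT volume, about
13 s per specimen), chosen so a complete 6-donor bilateral run finishes
in a few minutes on one core. Heavy primitives (3D median filter,
trilinear resampling, connected components, separable convolution) are
compiled; 2D morphology, hole filling and distance transforms come from
EBImage.

## Known limitations

* The phantom is geometrically idealized; conclusions about robustness to
  anatomy, orientation, beam hardening or scatter cannot be drawn from
  it.
* The deterministic lattice is shared across specimens; inter-specimen
  structural variation is represented only by the stochastic texture.
* DICOM parsing is out of scope; volumes arrive as NIfTI.
* Only density outputs are implemented for the segmentation workflow;
  trabecular morphometry (BV/TV, Tb.Th, Tb.Sp) is an extension point.
* Interactive reorientation is not implemented; synthetic volumes are
  axis-aligned, and real data should be reoriented upstream.
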