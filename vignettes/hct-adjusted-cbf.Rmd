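---
title: "Haematocrit-adjusted CBF quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haematocrit-adjusted CBF quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslhct)
```

## The quantification model

Pseudo-continuous arterial spin labelling (PCASL) measures perfusion by
magnetically inverting arterial blood water and imaging the labelled bolus
after a post-labelling delay (PLD). Under the simplified single-compartment
(Buxton) model, cerebral blood flow in mL/100 g/min is

$$
\mathrm{CBF} \;=\;
\frac{6000\,\lambda\; e^{\mathrm{PLD}/T_{1,\mathrm{blood}}}}
     {2\,\alpha\; T_{1,\mathrm{blood}}
       \left(1 - e^{-\tau/T_{1,\mathrm{blood}}}\right)}
\cdot \frac{S_C - S_L}{S_{PD}},
$$

where $\lambda$ is the blood/brain water partition coefficient (0.9 mL/g),
$\alpha$ the labelling efficiency (0.85), $\tau$ the labelling duration
(1800 ms), PLD the post-labelling delay (2000 ms), and $S_C$, $S_L$,
$S_{PD}$ the averaged control, label and proton-density signals. The
prefactor is exposed as `calibration_factor()`; everything to its right is
data. Times enter the model in seconds; the factor 6000 converts
mL/g/s to mL/100 g/min.

The single physiological parameter this package is about is
$T_{1,\mathrm{blood}}$. The consensus processing recommendation fixes it at
1650 ms, the value implied by an average adult haematocrit of 43.5% through
the relaxometry model

$$
T_{1,\mathrm{blood}} = \frac{1}{0.52\,\mathrm{Hct} + 0.38}\ \text{(s, Hct as a fraction)}.
$$

`t1_blood_from_hct()` evaluates this model and `quantify_subject()` accepts
either `"fixed"` (reference haematocrit) or a measured haematocrit
fraction. Because the acquired signal is identical under both choices,
their ratio per subject,

```{r}
hct_correction_ratio(c(0.388, 0.406, 0.435, 0.47))
```

is a deterministic, strictly increasing function of haematocrit that equals
1 at the reference. Women, some non-European ethnic groups and people with
diabetes have mean haematocrits several points below 43.5%, so the fixed
model systematically overestimates their CBF — by about 4% at Hct 40.6%
and 6.5% at Hct 38.8%. That overestimation, propagated through a realistic
cohort, is what the analysis scripts and acceptance checks quantify.

### Units and guards

Haematocrit is a fraction everywhere inside the package. The relaxometry
model rejects values outside [0.25, 0.55], which in practice catches
percent values passed unconverted; `read_cohort()` accepts percent-valued
columns (entries > 1) and converts them once at the boundary, refusing
files that mix conventions.

### Slice timing

The 2-D multi-slice readout acquires later slices at longer effective PLDs.
`sequence_params()` defaults to slice-timing correction on, with a 40 ms
per-slice increment (a typical 2-D EPI readout duration; the increment is
configurable). The correction is applied as a per-slice effective PLD
inside the kinetic model rather than as a post hoc intensity scaling — the
two are equivalent for the prefactor's exponential term, and the per-slice
form keeps the forward simulation and the quantification exactly
symmetric. One consequence worth knowing: the fixed-vs-individualised
ratio then varies slightly across slices (the PLD enters the exponent
multiplied by the difference of relaxation rates), so model-contrast
summaries quoted at "the" PLD refer to the nominal 2000 ms.

### Invalid voxels and negative CBF

Voxels with non-positive proton-density signal carry no calibration
reference and are marked `NA`, never zero — zeros would bias regional
means. Negative CBF values (noise-dominated voxels) are likewise retained;
the pipeline reports their fraction as a QC figure instead of clipping.

## Partial-volume handling

Tissue segmentations live on a much finer grid than 2-D ASL
(3.75 × 3.75 × 6 mm here). `resample_pv_with_psf()` carries them to the ASL
grid by smoothing with the acquisition point-spread function (Gaussian
in-plane, FWHM defaulting to one target voxel; delta through-plane) and
then box-averaging exactly into each target voxel. Both steps are convex
averages, so fractions stay in [0, 1] and tissue volume is conserved for
any phantom supported away from the field-of-view boundary (edges use
reflecting boundaries, the usual choice for in-vivo fields that end at the
head, not at the matrix edge).

`pvc_linear_regression()` unmixes grey- and white-matter perfusion by the
local two-tissue regression approach: in a kernel neighbourhood around each
voxel (default 5 × 5 × 1 — in-plane only, because 6 mm slices are close to
independent), the perfusion map is regressed without intercept on the GM
and WM fractions; CSF is modelled as non-perfused and therefore excluded
from the design. On a noiseless phantom whose neighbourhoods contain two
linearly independent tissue-fraction patterns the recovery is exact, which
the tests assert at 1e-8. Numerical choices:

* neighbourhoods whose design matrix has condition number above 1e6 are
  masked invalid (near-collinear fractions cannot be unmixed);
* pure single-tissue neighbourhoods fit that tissue alone and leave the
  other undetermined (`NA`) rather than fabricating a zero;
* all-background neighbourhoods are invalid, not zero.

`cortical_gm_mean()` then averages the GM coefficient map over valid
voxels with GM fraction ≥ 0.5 (threshold configurable), the summary used
for cohort statistics. Uncorrected cortical means sit below the PVC means
whenever CSF or WM dilutes the cortical voxels — the direction the
analysis scripts demonstrate.

## The synthetic cohort

No subject data ship with this package; the cohort module generates a
synthetic population whose haematocrit structure matches the published
summaries of a tri-ethnic elderly community cohort (493 subjects in six
sex-by-ethnicity strata). Per stratum, `generate_cohort()` draws:

* **Haematocrit** from a truncated normal on [0.25, 0.55] with the
  stratum's published mean and SD (men 43.8/42.0/43.0%, women
  40.6/38.8/38.8% for white European / South Asian / African Caribbean,
  SDs 2.4–3.6). Diabetics (stratum prevalences 17/37/32%) receive a
  1.3-point decrement applied mean-preservingly: non-diabetics shift up by
  $p\,\delta$ and diabetics down by $(1-p)\,\delta$, so the stratum mean is
  exactly preserved while the diabetic/non-diabetic contrast matches the
  published 40.7% vs 42.0%. (The decrement inflates stratum SDs by
  $p(1-p)\delta^2 \le 0.4$ points², under 2% — accepted.)
* **True cortical GM perfusion** with stratum means/SDs taken from the
  published individualised-model columns (44.5–51.1 ± 5.0–7.7
  mL/100 g/min), plus a within-stratum haematocrit coupling of
  −0.5 mL/100 g/min per haematocrit point around the stratum mean. The
  coupling magnitude is a modelling choice, not a published value: the
  source material shows an inverse Hct–CBF relation that survives
  correction in men but does not quantify the within-subject slope. The
  residual SD is reduced so the marginal stratum SD matches the published
  one. Setting the slope to 0 is supported.
* **Covariates** (age, BMI, lipids, HbA1c, mean arterial pressure) from
  the published sex- or ethnicity-level means/SDs; LDL is derived from
  total cholesterol, HDL and triglycerides through the Friedewald relation
  (`ldl_friedewald()`), flagged missing above its 4.52 mmol/L validity
  bound.

All draws derive from a single cohort-level seed, so a cohort is
reproducible bit for bit.

What this generator deliberately does **not** emulate: real anatomy (the
phantom is a concentric ellipsoid), arterial transit-time heterogeneity,
motion or susceptibility artefacts, and any between-covariate correlation
structure beyond the haematocrit couplings above. Tests passing on this
cohort therefore validate the quantification and statistics machinery and
the haematocrit arithmetic — not the behaviour of the pipeline on real,
artefact-laden acquisitions.

### Forward simulation

`simulate_acquisition()` inverts the kinetic model: the expected
perfusion-weighted ratio per voxel and slice is
$\mathrm{CBF}_{\mathrm{true}} / \mathrm{factor}(T_1(\mathrm{Hct}),
\mathrm{PLD}_z)$; control/label repeats are generated around a
background-suppressed static signal (25% of PD) with independent Gaussian
noise per repeat (default SD 0.5% of the PD level — with 35 averaged pairs
this puts single-voxel CBF noise at roughly 10% of a GM value, a
mid-range ASL operating point), and PD repeats scale with voxel water
content so background quantifies as invalid. The noiseless round trip
through `quantify_subject()` is exact to machine precision and is asserted
at 1e-8 in the tests; under noise, grey-matter recovery is unbiased
(asserted below 1% over 25 replicate acquisitions).

For cohort-scale work the voxelwise route is unnecessarily heavy: the
scalar route (`quantify_signal_ratio()`) applies the same model to one
perfusion-weighted ratio per subject at the nominal PLD. The fixed/Hct
contrast per subject is identical along both routes because the signal
cancels from the ratio.

## Cohort statistics

`paired_comparison()` performs the paired t test between models and
reports Cohen's d in the pooled-SD-of-the-two-measures form
$d = |\overline{\Delta}| / \sqrt{(s^2_{\mathrm{fixed}} +
s^2_{\mathrm{Hct}})/2}$. The SD-of-differences form would be the other
textbook option, but for this contrast the two measurement sets are almost
perfectly correlated, which deflates the difference SD and would inflate d
by an order of magnitude; the pooled form is also the only one that
reproduces the published effect sizes from their printed summary
statistics (the tests verify all fourteen published values, to the
precision the 1-decimal-printed inputs admit, ≤ 0.015 in d).

Percent differences between models are ambiguous in aggregate, so
`percent_difference_summary()` reports both definitions: the per-subject
mean of $100(\mathrm{CBF}_{\mathrm{Hct}} -
\mathrm{CBF}_{\mathrm{fixed}})/\mathrm{CBF}_{\mathrm{fixed}}$ (primary —
it is signal-independent, each subject's percentage being a deterministic
function of haematocrit) and the ratio of cohort means (secondary). At a
single subject they coincide.

`two_way_anova_lsd()` uses Type II sums of squares (via `car::Anova`)
because the cell counts are unbalanced and the reference-group comparisons
assume no appreciable interaction; Fisher's LSD follow-up against the
reference level runs only when the corresponding main effect is
significant at 0.05, with no further multiplicity correction — that is
what LSD means. `linear_adjusted_model()` is ordinary least squares with
listwise deletion (count logged) and a hard error on rank deficiency
naming the collinear columns. `kernel_density()` wraps a Gaussian KDE with
Silverman's rule-of-thumb bandwidth by default; the tests assert the
trapezoidal integral is 1 within 1e-3.

## Problem sizes and reproducibility

The test-suite and analysis problem sizes are chosen at desk scale: the
phantom defaults to 24 × 24 × 8 voxels (16 × 16 × 6 in tests), cohorts to
the published 493 subjects, and replicate counts to 25–100 depending on
the Monte-Carlo error a check needs. The stratified percent-difference
checks average 100 cohort replicates, which puts their Monte-Carlo SE
near 0.02 percentage points — far inside the ±0.3-point band they are
compared at. `run_pipeline()` snapshots every stage (parameters, seeds,
output hashes) into a manifest, and identical configurations reproduce
outputs bit for bit.

## Known limitations

* The per-subject model contrast is exact arithmetic; simulated
  between-subject SDs, t statistics and p values depend on the generator's
  variance structure (physiological SD, Hct coupling), for which no
  published per-subject values exist — they are plausible rather than
  calibrated, and the simulated absolute mean difference in women runs
  ~0.1 mL/100 g/min above the published 2.7 because low-Hct subjects have
  both inflated fixed-model CBF and larger corrections (a covariance the
  printed summaries cannot constrain).
* Labelling efficiency is a single global α; background suppression enters
  only as a static-signal scale, not a pulse-timing model.
* The PVC kernel is in-plane; through-plane mixing across 6 mm slices is
  not corrected.
* Single-PLD quantification ignores arterial transit time; no multi-delay
  kinetic fitting is provided.
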