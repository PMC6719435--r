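# aslhct

Haematocrit-adjusted cerebral blood flow (CBF) quantification from
pseudo-continuous arterial spin labelling (PCASL), with partial-volume
correction and the stratified cohort statistics needed to compare the
standard fixed-blood-T1 model against per-subject haematocrit correction.

## The problem

ASL quantification converts a perfusion-weighted signal into CBF through
the simplified single-compartment (Buxton) model

```
CBF = 6000 λ e^(PLD/T1b) / (2 α T1b (1 − e^(−τ/T1b))) · (SC − SL)/SPD   [mL/100 g/min]
```

with λ = 0.9 mL/g, α = 0.85, τ = 1800 ms, PLD = 2000 ms. Standard
processing fixes the blood relaxation time T1b at 1650 ms — the value the
relaxometry model `T1b = 1/(0.52·Hct + 0.38)` gives at an average adult
haematocrit of 43.5%. But haematocrit varies systematically with sex,
ethnicity and diabetes status: women and several non-European groups
average 39–41%. Since the acquired signal is the same either way, the
fixed-T1 model inflates their CBF by a deterministic, haematocrit-dependent
factor — about 4% at Hct 40.6% and 6.5% at 38.8%. This package implements
both models, the correction ratio between them, PSF-aware partial-volume
map resampling, local-regression partial-volume correction (PVC), a
synthetic tri-ethnic elderly cohort generator, and the paired/stratified
statistics that quantify the bias at population scale. It is aimed at
perfusion-MRI methods researchers and at anyone checking how much a fixed
haematocrit assumption distorts group comparisons.

## Worked example

```r
library(aslhct)

t1_blood_from_hct(0.435)
#> blood T1: 1649.6 ms (Hct 43.5%)

hct_correction_ratio(0.388)     # African Caribbean women's mean Hct
#> [1] 0.9351702                 # fixed model overestimates CBF by 6.5%

## voxelwise: simulate a low-Hct subject, quantify both ways, apply PVC
params  <- sequence_params()
phantom <- make_phantom(phantom_spec())          # GM 60, WM 20 mL/100g/min
acq     <- simulate_acquisition(phantom, hct = 0.373, params, seed = 1)
fixed   <- quantify_subject(acq, params, "fixed")
indiv   <- quantify_subject(acq, params, 0.373)
pvc     <- pvc_linear_regression(indiv$cbf, phantom$pv)
cortical_gm_mean(pvc, phantom$pv$pv_gm)$mean_cbf
#> [1] 60.37245
```

For this subject (Hct 37.3%) the uncorrected cortical GM means are 61.0
(fixed) vs 55.6 (individualised) mL/100 g/min against a ground truth of
60: partial-volume dilution pulls the uncorrected mean down, the fixed-T1
assumption pushes it up by 8.5%, and PVC plus haematocrit correction
recovers 60.4.

The full cohort analysis runs as four scripts:

```sh
Rscript analysis/01_simulate_cohort.R    # 493 subjects, 6 strata -> results/cohort.csv
Rscript analysis/02_quantify_cbf.R       # both models per subject
Rscript analysis/03_phantom_pvc.R        # voxelwise + PVC demonstration
Rscript analysis/04_cohort_statistics.R  # stratified contrasts, ANOVA, KDE
```

At seed 1 the stratified report (`results/model_comparison.csv`) shows the
individualised model sitting below the fixed model by 2.6% across the
cohort, 5.7% in women (mean difference −3.0 mL/100 g/min, d = 0.45) and
essentially zero in white European men — the haematocrit-driven pattern
the package exists to expose. The haematocrit–CBF correlation of −0.37
under the fixed model collapses to −0.02 after correction.

## Package layout

- `R/` — quantification (`sequence_params`, `t1_blood_from_hct`,
  `calibration_factor`, `quantify_subject`), PVC
  (`resample_pv_with_psf`, `pvc_linear_regression`, `cortical_gm_mean`),
  synthetic data (`generate_cohort`, `make_phantom`,
  `simulate_acquisition`), statistics (`paired_comparison`,
  `percent_difference_summary`, `two_way_anova_lsd`,
  `linear_adjusted_model`, `kernel_density`), IO and the pipeline driver
  (`read_volume`, `read_cohort`, `read_config`, `run_pipeline`).
- `analysis/` — the numbered workflow above.
- `vignettes/hct-adjusted-cbf.Rmd` — model assumptions, parameter
  defaults, generator design and limitations.
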