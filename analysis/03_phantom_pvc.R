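#!/usr/bin/env Rscript
# Voxelwise demonstration: phantom acquisition, both models, PVC.
#
# Simulates a full noisy ASL acquisition of the digital phantom for a
# low-haematocrit subject, quantifies it with the fixed and the
# individualised model, applies partial-volume correction and extracts the
# cortical grey-matter mean each way. Also demonstrates the PSF-aware
# resampling path from a high-resolution segmentation to the ASL grid.

library(aslhct)

seed <- 1L
params <- sequence_params()
phantom <- make_phantom(phantom_spec())
hct <- 0.373  # the worked low-Hct example subject

acq <- simulate_acquisition(phantom, hct, params, seed = seed)
map_fixed <- quantify_subject(acq, params, "fixed")
map_hct <- quantify_subject(acq, params, hct)

pvc_fixed <- pvc_linear_regression(map_fixed$cbf, phantom$pv)
pvc_hct <- pvc_linear_regression(map_hct$cbf, phantom$pv)
gm_fixed <- cortical_gm_mean(pvc_fixed, phantom$pv$pv_gm)
gm_hct <- cortical_gm_mean(pvc_hct, phantom$pv$pv_gm)

# uncorrected cortical means over the same mask, for the PVC contrast
mask <- phantom$pv$pv_gm >= 0.5 & is.finite(map_hct$cbf)
unc_fixed <- mean(map_fixed$cbf[mask])
unc_hct <- mean(map_hct$cbf[mask])

dir.create("results", showWarnings = FALSE)
write_volume(map_fixed, "results/phantom_cbf_fixed.nii.gz")
write_volume(map_hct, "results/phantom_cbf_hct.nii.gz")
write_volume(pvc_hct$gm_cbf_map, "results/phantom_gm_pvc.nii.gz",
             grid = phantom$grid)

summary <- data.frame(
  model = c("fixed", "hct"),
  uncorrected_gm = c(unc_fixed, unc_hct),
  pvc_gm = c(gm_fixed$mean_cbf, gm_hct$mean_cbf),
  n_voxels = c(gm_fixed$n_voxels, gm_hct$n_voxels))
write.csv(summary, "results/pvc_summary.csv", row.names = FALSE)

message(sprintf(
  "subject Hct %.1f%%: fixed model GM %.1f (PVC %.1f), individualised %.1f
(PVC %.1f) mL/100g/min; true GM perfusion is %.0f -- PVC removes the
partial-volume dilution and the Hct model removes the %.1f%% overestimate",
  100 * hct, unc_fixed, gm_fixed$mean_cbf, unc_hct, gm_hct$mean_cbf,
  phantom$spec$gm_cbf, 100 * (1 - hct_correction_ratio(hct, params))))
print(summary, row.names = FALSE)

# resampling demonstration: a finer segmentation grid down to the ASL grid
hi_spec <- phantom_spec(dim = c(72, 72, 8), pixdim = c(1.25, 1.25, 6))
hi <- make_phantom(hi_spec)
lo <- resample_pv_with_psf(hi$pv, phantom$grid)
message(sprintf(
  "PSF-aware resampling 72x72 -> 24x24: GM volume fraction %.4f -> %.4f",
  mean(hi$pv$pv_gm), mean(lo$pv_gm)))
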