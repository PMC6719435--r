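test_that("PSF-aware resampling preserves constant fields and mass", {
  d_hi <- c(24, 24, 4)
  grid_hi <- asl_grid(d_hi, pixdim = c(1.25, 1.25, 6))
  grid_lo <- asl_grid(c(8, 8, 4), pixdim = c(3.75, 3.75, 6))
  # uniform GM fraction is a fixed point of smoothing + box averaging
  pv <- pv_maps(array(0.6, d_hi), array(0.3, d_hi), array(0.1, d_hi),
                grid = grid_hi)
  out <- resample_pv_with_psf(pv, grid_lo)
  expect_equal(as.vector(out$pv_gm), rep(0.6, 8 * 8 * 4), tolerance = 1e-12)
  expect_equal(as.vector(out$pv_csf), rep(0.1, 8 * 8 * 4), tolerance = 1e-12)
  # a 50/50 GM/WM checkerboard averages to exactly one-half per 2x2 block
  chk <- array(as.numeric((slice.index(array(0, d_hi), 1) +
                             slice.index(array(0, d_hi), 2)) %% 2), d_hi)
  pv2 <- pv_maps(chk, 1 - chk, array(0, d_hi), grid = grid_hi)
  grid_half <- asl_grid(c(12, 12, 4), pixdim = c(2.5, 2.5, 6))
  out2 <- resample_pv_with_psf(pv2, grid_half, psf_fwhm_mm = 0)
  expect_equal(as.vector(out2$pv_gm), rep(0.5, 12 * 12 * 4),
               tolerance = 1e-12)
  # with the default PSF, interior voxels still average to one-half
  out2g <- resample_pv_with_psf(pv2, grid_half)
  expect_equal(as.vector(out2g$pv_gm[4:9, 4:9, ]),
               rep(0.5, 6 * 6 * 4), tolerance = 1e-9)
  # total tissue mass is conserved on a closed phantom (tissue supported
  # well inside the field of view, so no boundary interaction)
  d_c <- c(32, 32, 4)
  gm <- array(0, d_c); gm[13:20, 13:20, ] <- 0.7
  wm <- array(0, d_c); wm[13:20, 13:20, ] <- 0.2
  cs <- array(0, d_c); cs[13:20, 13:20, ] <- 0.1
  hi <- pv_maps(gm, wm, cs, grid = asl_grid(d_c, pixdim = c(1.25, 1.25, 6)))
  lo <- resample_pv_with_psf(hi, asl_grid(c(8, 8, 4),
                                          pixdim = c(5, 5, 6)))
  total_hi <- mean(hi$pv_gm + hi$pv_wm + hi$pv_csf)
  total_lo <- mean(lo$pv_gm + lo$pv_wm + lo$pv_csf)
  expect_equal(total_lo, total_hi, tolerance = 1e-6)
  # fractions stay within [0, 1] and sum <= 1
  expect_true(max(lo$pv_gm + lo$pv_wm + lo$pv_csf) <= 1 + 1e-6)
  # incompatible extents are rejected
  expect_error(resample_pv_with_psf(hi, asl_grid(c(8, 8, 4),
                                                 pixdim = c(2, 2, 6))),
               "incompatible affines")
})

test_that("local regression recovers tissue perfusion exactly without noise", {
  ph <- small_phantom()           # GM 60, WM 20 by construction
  pvc <- pvc_linear_regression(ph$true_cbf, ph$pv, kernel = c(5, 5, 1))
  gm_err <- abs(pvc$gm_cbf_map[pvc$valid & ph$pv$pv_gm > 0.2] - 60)
  expect_lt(max(gm_err), 1e-8)
  wm_vox <- pvc$valid & ph$pv$pv_wm > 0.2 & is.finite(pvc$wm_cbf_map)
  expect_lt(max(abs(pvc$wm_cbf_map[wm_vox] - 20)), 1e-8)
})

test_that("PVC leaves a uniform map over pure tissue unchanged", {
  d <- c(9, 9, 1)
  pv <- pv_maps(array(1, d), array(0, d), grid = asl_grid(d))
  cbf <- array(47.3, d)
  pvc <- pvc_linear_regression(cbf, pv, kernel = c(3, 3, 1))
  expect_true(all(pvc$valid))
  expect_equal(as.vector(pvc$gm_cbf_map), rep(47.3, prod(d)),
               tolerance = 1e-12)
  # WM is undetermined in a pure-GM region, not fabricated
  expect_true(all(is.na(pvc$wm_cbf_map)))
})

test_that("degenerate neighbourhoods are masked invalid, not zeroed", {
  d <- c(9, 9, 1)
  gm <- array(0, d); gm[4:6, 4:6, 1] <- 1
  pv <- pv_maps(gm, array(0, d), grid = asl_grid(d))
  cbf <- array(0, d); cbf[4:6, 4:6, 1] <- 55
  pvc <- pvc_linear_regression(cbf, pv, kernel = c(3, 3, 1))
  # corner voxels have all-zero tissue in their window -> invalid
  expect_false(pvc$valid[1, 1, 1])
  expect_true(is.na(pvc$gm_cbf_map[1, 1, 1]))
  # the tissue block itself is recovered
  expect_equal(pvc$gm_cbf_map[5, 5, 1], 55, tolerance = 1e-10)
  # kernel validation
  expect_error(pvc_linear_regression(cbf, pv, kernel = c(4, 4, 1)), "odd")
  expect_error(pvc_linear_regression(cbf, pv, kernel = c(11, 11, 3)),
               "fit inside")
})

test_that("noisy PVC recovery is unbiased within Monte-Carlo error", {
  ph <- small_phantom()
  set.seed(31)
  n_rep <- 12
  gm_means <- replicate(n_rep, {
    noisy <- ph$true_cbf + array(rnorm(length(ph$true_cbf), 0, 5),
                                 dim(ph$true_cbf))
    pvc <- pvc_linear_regression(noisy, ph$pv, kernel = c(5, 5, 1))
    cortical_gm_mean(pvc, ph$pv$pv_gm, 0.5)$mean_cbf
  })
  se <- sd(gm_means) / sqrt(n_rep)
  expect_lt(abs(mean(gm_means) - 60), max(4 * se, 0.5))
})

test_that("cortical grey-matter mean respects threshold and validity", {
  ph <- small_phantom()
  pvc <- pvc_linear_regression(ph$true_cbf, ph$pv, kernel = c(5, 5, 1))
  gm <- cortical_gm_mean(pvc, ph$pv$pv_gm, threshold = 0.5)
  expect_equal(gm$mean_cbf, 60, tolerance = 1e-8)
  expect_gt(gm$n_voxels, 0)
  # stricter threshold uses fewer voxels
  gm_strict <- cortical_gm_mean(pvc, ph$pv$pv_gm, threshold = 0.99)
  expect_lte(gm_strict$n_voxels, gm$n_voxels)
  # no voxel reaches an impossible threshold on an all-mixed phantom
  mixed <- pv_maps(array(0.5, c(7, 7, 1)), array(0.5, c(7, 7, 1)),
                   grid = asl_grid(c(7, 7, 1)))
  pvc2 <- pvc_linear_regression(array(40, c(7, 7, 1)), mixed,
                                kernel = c(3, 3, 1))
  expect_error(cortical_gm_mean(pvc2, mixed$pv_gm, threshold = 1.0),
               "empty cortical mask")
  expect_error(cortical_gm_mean(pvc, ph$pv$pv_gm, threshold = 1.5),
               "threshold")
})
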