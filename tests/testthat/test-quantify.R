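test_that("voxelwise quantification agrees with the literal model", {
  sp <- sequence_params(slice_timing_enabled = FALSE)
  t1 <- t1_blood_from_hct(0.42)
  set.seed(11)
  d <- c(6, 5, 4)
  sc <- array(runif(prod(d), 100, 200), d)
  sl <- sc - array(runif(prod(d), 0, 2), d)
  pd <- array(runif(prod(d), 500, 1500), d)
  cbf <- cbf_from_signals(sc, sl, pd, sp, t1)
  oracle <- eq1_cbf_literal(sc, sl, pd, t1$t1_seconds)
  expect_lt(max(abs(cbf - oracle) / abs(oracle)), 1e-10)
})

test_that("quantification respects per-slice effective PLDs", {
  sp <- sequence_params(n_slices = 4, slice_duration = 50)
  t1 <- t1_blood_from_hct(0.40)
  d <- c(3, 3, 4)
  sc <- array(101, d); sl <- array(100, d); pd <- array(1000, d)
  cbf <- cbf_from_signals(sc, sl, pd, sp, t1)
  for (z in 1:4) {
    oracle <- eq1_cbf_literal(101, 100, 1000, t1$t1_seconds,
                              pld_ms = 2000 + (z - 1) * 50)
    expect_equal(cbf[1, 1, z], oracle, tolerance = 1e-12)
  }
  # later slices see more label decay -> larger scaling of the same signal
  expect_true(all(diff(cbf[1, 1, ]) > 0))
})

test_that("degenerate signals behave by convention", {
  sp <- sequence_params()
  t1 <- t1_blood_from_hct(0.435)
  d <- c(4, 4, 2)
  sc <- array(100, d); pd <- array(1000, d)
  # control = label -> zero perfusion everywhere
  expect_true(all(cbf_from_signals(sc, sc, pd, sp, t1) == 0))
  # doubling both difference and PD leaves CBF unchanged
  sl <- sc - 1
  a <- cbf_from_signals(sc, sl, pd, sp, t1)
  b <- cbf_from_signals(2 * sc, 2 * sl, 2 * pd, sp, t1)
  expect_equal(a, b, tolerance = 1e-12)
  # negative differences give negative CBF, not clipped
  neg <- cbf_from_signals(sl, sc, pd, sp, t1)
  expect_true(all(neg < 0))
  # SPD <= 0 voxels are invalid, never zero
  pd_bad <- pd; pd_bad[1, 1, 1] <- 0; pd_bad[2, 2, 2] <- -5
  out <- cbf_from_signals(sc, sl, pd_bad, sp, t1)
  expect_true(is.na(out[1, 1, 1]) && is.na(out[2, 2, 2]))
  expect_equal(sum(is.na(out)), 2)
  # all-invalid input is an error
  expect_error(cbf_from_signals(sc, sl, array(0, d), sp, t1), "no valid")
})

test_that("repeat averaging is the voxelwise arithmetic mean", {
  d <- c(5, 4, 3)
  one <- array(rnorm(prod(d)), d)
  # identical repeats average to themselves; single repeats are identity
  stack35 <- array(one, c(d, 35))
  acq <- asl_acquisition(stack35, stack35, array(one, c(d, 1)))
  av <- average_repeats(acq)
  expect_equal(av$mean_control, one, tolerance = 1e-12)
  expect_equal(av$mean_pd, one, tolerance = 1e-12)
  expect_equal(av$n_pairs, 35)
  # zero-mean noise shrinks as 1/sqrt(n): mean within 5 sd/sqrt(n) of truth
  set.seed(21)
  noise_sd <- 2
  noisy <- array(one, c(d, 35)) +
    array(rnorm(prod(d) * 35, 0, noise_sd), c(d, 35))
  acq2 <- asl_acquisition(noisy, noisy, array(one, c(d, 1)))
  err <- max(abs(average_repeats(acq2)$mean_control - one))
  expect_lt(err, 5 * noise_sd / sqrt(35))
  # mismatched grids are rejected
  expect_error(asl_acquisition(stack35, stack35[, , 1:2, ],
                               array(one, c(d, 1))), "share one grid")
  expect_error(asl_acquisition(stack35, stack35[, , , 1:10],
                               array(one, c(d, 1))), "repeat counts")
})

test_that("fixed and individualised models differ by the correction ratio", {
  ph <- small_phantom()
  sp <- sequence_params(slice_timing_enabled = FALSE)
  hct <- 0.39
  acq <- simulate_acquisition(ph, hct, sp, noise_sd = 0.002, seed = 5)
  m_fixed <- quantify_subject(acq, sp, "fixed")
  m_hct <- quantify_subject(acq, sp, hct)
  expect_identical(m_fixed$model, "fixed")
  expect_identical(m_hct$model, "hct")
  expect_equal(1000 * m_fixed$t1_blood_used, 1650, tolerance = 0.5)
  # voxelwise ratio is spatially constant and equals hct_correction_ratio,
  # even in the presence of noise (the signal cancels exactly)
  ok <- is.finite(m_fixed$cbf) & abs(m_fixed$cbf) > 1e-6
  ratio <- m_hct$cbf[ok] / m_fixed$cbf[ok]
  expect_lt(diff(range(ratio)), 1e-12)
  expect_equal(ratio[1], hct_correction_ratio(hct, sp), tolerance = 1e-12)
  # below-reference haematocrit: individualised CBF is lower wherever the
  # measured perfusion is positive (the ratio preserves sign)
  pos <- ok & m_fixed$cbf > 0
  expect_true(all(m_hct$cbf[pos] < m_fixed$cbf[pos]))
})

test_that("with slice timing on, the model ratio is constant within slice", {
  ph <- small_phantom()
  sp <- sequence_params()
  hct <- 0.47
  acq <- simulate_acquisition(ph, hct, sp, noise_sd = 0, seed = 1)
  m_fixed <- quantify_subject(acq, sp, "fixed")
  m_hct <- quantify_subject(acq, sp, hct)
  for (z in c(1, 4, 6)) {
    ok <- is.finite(m_fixed$cbf[, , z]) & m_fixed$cbf[, , z] > 1e-6
    if (!any(ok)) next
    ratio <- (m_hct$cbf[, , z])[ok] / (m_fixed$cbf[, , z])[ok]
    expect_lt(diff(range(ratio)), 1e-12)
    expect_equal(ratio[1],
                 hct_correction_ratio(hct, sp,
                                      pld_override = slice_effective_pld(sp, z - 1)),
                 tolerance = 1e-12)
  }
})

test_that("scalar cohort quantification matches the correction ratio", {
  sp <- sequence_params()
  hct <- c(0.30, 0.40, 0.435, 0.50)
  out <- quantify_signal_ratio(rep(5.131e-3, 4), hct, sp)
  # spec example: ratio 5.131e-3 at defaults is ~50 mL/100 g/min
  expect_equal(out$cbf_fixed[1], 50.0, tolerance = 2e-4)
  expect_equal(out$cbf_hct / out$cbf_fixed, hct_correction_ratio(hct, sp),
               tolerance = 1e-12)
  # exact agreement of both models at the reference haematocrit
  expect_equal(out$cbf_hct[3], out$cbf_fixed[3], tolerance = 1e-12)
})
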