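#' Voxelwise CBF from averaged ASL signals
#'
#' Applies the simplified Buxton single-compartment quantification
#' voxelwise: `CBF = factor * (SC - SL) / SPD` with the factor from
#' [calibration_factor()]. With slice timing enabled each axial slice uses
#' its own effective PLD. Voxels with `SPD <= 0` carry no signal reference
#' and are marked invalid (`NA`), never silently zero; negative differences
#' produce negative CBF and are retained (clipping would bias regional
#' means).
#'
#' @param mean_control,mean_label,mean_pd 3-D arrays on a common grid.
#' @param params A [sequence_params()] object.
#' @param t1 A `blood_t1` object.
#' @return A 3-D array of CBF in mL/100 g/min, `NA` where invalid.
#' @export
cbf_from_signals <- function(mean_control, mean_label, mean_pd, params, t1) {
  stopifnot(inherits(params, "sequence_params"), inherits(t1, "blood_t1"))
  d <- dim(mean_control)
  if (is.null(d) || length(d) != 3L)
    stop("signal inputs must be 3-D arrays", call. = FALSE)
  if (!identical(d, dim(mean_label)) || !identical(d, dim(mean_pd)))
    stop("signal inputs must share one grid", call. = FALSE)
  valid <- is.finite(mean_pd) & mean_pd > 0
  if (!any(valid))
    stop("no valid voxels: proton-density reference is nowhere positive",
         call. = FALSE)
  nz <- d[3]
  if (nz > params$n_slices)
    stop(sprintf("volume has %d slices but the sequence declares %d",
                 nz, params$n_slices), call. = FALSE)
  pld_z <- slice_effective_pld(params, seq_len(nz) - 1L)
  ratio <- (mean_control - mean_label) / mean_pd
  cbf <- array(NA_real_, d)
  for (z in seq_len(nz)) {
    f <- calibration_factor(params, t1, pld_override = pld_z[z])
    cbf[, , z] <- f * ratio[, , z]
  }
  cbf[!valid] <- NA_real_
  cbf
}

#' Perfusion map container
#'
#' @param cbf 3-D array of CBF, mL/100 g/min (`NA` = invalid voxel).
#' @param model `"fixed"` or `"hct"`.
#' @param t1_blood_used Blood T1 used, seconds.
#' @param grid An [asl_grid()] descriptor.
#' @param hct Haematocrit fraction behind `t1_blood_used` (`NA` for fixed).
#' @return An object of class `perfusion_map`.
#' @export
perfusion_map <- function(cbf, model, t1_blood_used, grid, hct = NA_real_) {
  model <- match.arg(model, c("fixed", "hct"))
  stopifnot(length(dim(cbf)) == 3L, inherits(grid, "asl_grid"))
  structure(list(cbf = cbf, model = model, t1_blood_used = t1_blood_used,
                 hct = hct, grid = grid),
            class = "perfusion_map")
}

#' @export
print.perfusion_map <- function(x, ...) {
  v <- x$cbf[is.finite(x$cbf)]
  cat(sprintf(
    "perfusion map (%s model, T1_blood %.0f ms): %s grid, %d valid voxels\n",
    x$model, 1000 * x$t1_blood_used, paste(x$grid$dim, collapse = "x"),
    length(v)))
  if (length(v))
    cat(sprintf("  CBF mean %.1f, range [%.1f, %.1f] mL/100g/min; %.1f%% negative\n",
                mean(v), min(v), max(v), 100 * mean(v < 0)))
  invisible(x)
}

#' Quantify one subject's acquisition
#'
#' Full single-subject quantification: average the repeats, then apply the
#' kinetic model slice by slice. `hct = "fixed"` uses the reference
#' haematocrit of the sequence (the standard fixed-T1 model); a numeric
#' fraction uses the subject's measured haematocrit (the individualised
#' model).
#'
#' @param acq An [asl_acquisition()] object.
#' @param params A [sequence_params()] object.
#' @param hct `"fixed"` or a haematocrit fraction.
#' @return A [perfusion_map()] tagged with the model and blood T1 used.
#' @export
quantify_subject <- function(acq, params = sequence_params(), hct = "fixed") {
  stopifnot(inherits(acq, "asl_acquisition"))
  fixed <- identical(hct, "fixed")
  t1 <- if (fixed) t1_blood_from_hct(params$hct_reference)
        else t1_blood_from_hct(hct)
  av <- average_repeats(acq)
  cbf <- cbf_from_signals(av$mean_control, av$mean_label, av$mean_pd,
                          params, t1)
  perfusion_map(cbf, model = if (fixed) "fixed" else "hct",
                t1_blood_used = t1$t1_seconds, grid = acq$grid,
                hct = if (fixed) NA_real_ else hct)
}

#' Subject-level CBF under both models from a perfusion-weighted ratio
#'
#' Scalar counterpart of the voxelwise pipeline for cohort work: given each
#' subject's measured perfusion-weighted signal ratio `(SC - SL)/SPD`
#' (e.g. a cortical grey-matter mean) and haematocrit, returns the CBF that
#' the fixed-reference model and the Hct-individualised model assign to it.
#' Evaluated at the nominal PLD. The ratio `cbf_hct / cbf_fixed` equals
#' [hct_correction_ratio()] by construction.
#'
#' @param signal_ratio Per-subject `(SC - SL)/SPD`, dimensionless.
#' @param hct Per-subject haematocrit fraction, same length.
#' @param params A [sequence_params()] object.
#' @return A data frame with columns `cbf_fixed` and `cbf_hct` (mL/100 g/min).
#' @export
quantify_signal_ratio <- function(signal_ratio, hct,
                                  params = sequence_params()) {
  stopifnot(length(signal_ratio) == length(hct))
  f_ref <- calibration_factor(params, t1_blood_from_hct(params$hct_reference))
  f_subj <- calibration_factor(params, t1_blood_from_hct(hct))
  data.frame(cbf_fixed = f_ref * signal_ratio,
             cbf_hct = f_subj * signal_ratio)
}
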