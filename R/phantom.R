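#' Phantom specification
#'
#' Geometry and signal settings of a synthetic brain-like phantom: a
#' concentric ellipsoid with a white-matter core, a cortical grey-matter
#' ribbon and an outer CSF rim, embedded in signal-free background. Tissue
#' fractions at region boundaries are computed by subvoxel supersampling,
#' so the phantom contains pure-GM, pure-WM and mixed voxels.
#'
#' @param dim Grid dimensions, default `c(24, 24, 8)`.
#' @param pixdim Voxel size mm, default `c(3.75, 3.75, 6)` (2-D ASL-like).
#' @param gm_cbf,wm_cbf True tissue perfusion, mL/100 g/min.
#' @param pd_level Proton-density signal level of pure tissue, a.u.
#' @param bs_scale Static-signal scale of the background-suppressed ASL
#'   images relative to PD.
#' @param noise_sd Gaussian noise SD per repeat, relative to `pd_level`.
#' @param n_pairs,n_pd Default control/label pair and PD repeat counts.
#' @param radii Normalised radii `(wm, gm, csf)` of the concentric regions.
#' @param supersample Subvoxel sampling factor per axis for boundary
#'   fractions.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(24, 24, 8), pixdim = c(3.75, 3.75, 6),
                         gm_cbf = 60, wm_cbf = 20, pd_level = 1000,
                         bs_scale = 0.25, noise_sd = 0.005,
                         n_pairs = 35, n_pd = 3,
                         radii = c(0.45, 0.80, 0.95), supersample = 3) {
  if (any(dim[1:2] < 6) || dim[3] < 2)
    stop("grid too small for the concentric geometry", call. = FALSE)
  if (gm_cbf < 0 || wm_cbf < 0)
    stop("perfusion must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (!all(diff(radii) > 0) || any(radii <= 0) || any(radii > 1))
    stop("radii must be increasing in (0, 1]", call. = FALSE)
  structure(list(dim = as.integer(dim), pixdim = as.numeric(pixdim),
                 gm_cbf = gm_cbf, wm_cbf = wm_cbf, pd_level = pd_level,
                 bs_scale = bs_scale, noise_sd = noise_sd,
                 n_pairs = as.integer(n_pairs), n_pd = as.integer(n_pd),
                 radii = radii, supersample = as.integer(supersample)),
            class = "phantom_spec")
}

#' Build the phantom tissue maps and true perfusion
#'
#' Deterministic (no randomness): returns the partial-volume maps of the
#' concentric GM/WM/CSF geometry and the true perfusion map
#' `gm_cbf * pv_gm + wm_cbf * pv_wm` (CSF does not perfuse).
#'
#' @param spec A [phantom_spec()] object.
#' @return A list with `pv` ([pv_maps()]), `true_cbf` (3-D array), `grid`
#'   and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  s <- spec$supersample
  # subvoxel centres in normalised [-1, 1] coordinates per axis
  coords <- lapply(1:3, function(a) {
    n <- d[a] * s
    ((seq_len(n) - 0.5) / n) * 2 - 1
  })
  r_xy <- outer(coords[[1]]^2, coords[[2]]^2, `+`)
  rho2 <- outer(r_xy, coords[[3]]^2, `+`)
  rho <- sqrt(rho2)
  lab <- array(0L, dim(rho))                 # 0 background
  lab[rho <= spec$radii[3]] <- 3L            # CSF rim
  lab[rho <= spec$radii[2]] <- 1L            # GM ribbon
  lab[rho <= spec$radii[1]] <- 2L            # WM core
  frac <- function(code)
    block_average(array(as.numeric(lab == code), dim(lab)), c(s, s, s))
  grid <- asl_grid(d, spec$pixdim)
  pv <- pv_maps(frac(1L), frac(2L), frac(3L), grid = grid)
  if (!any(pv$pv_gm == 1) || !any(pv$pv_wm == 1))
    stop("grid too small for the geometry: no pure-tissue voxels",
         call. = FALSE)
  true_cbf <- spec$gm_cbf * pv$pv_gm + spec$wm_cbf * pv$pv_wm
  list(pv = pv, true_cbf = true_cbf, grid = grid, spec = spec)
}

#' Forward-simulate an ASL acquisition
#'
#' Inverts the quantification model: for a subject with haematocrit `hct`,
#' the expected perfusion-weighted ratio in each voxel and slice is
#' `true_cbf / calibration_factor(params, t1(hct), pld_slice)`. Control and
#' label repeats are generated around the background-suppressed static
#' signal with `control - label` equal to the labelled magnetisation in
#' expectation; proton-density repeats scale with total water content
#' (tissue plus CSF), so background voxels have no PD signal and quantify
#' as invalid. Independent Gaussian noise is added per repeat and voxel.
#'
#' @param phantom A [make_phantom()] result.
#' @param hct Subject haematocrit fraction (or `"fixed"` to simulate a
#'   subject at the reference haematocrit).
#' @param params A [sequence_params()] object.
#' @param noise_sd Noise SD relative to the PD level; default from the
#'   phantom spec, use 0 for a noiseless acquisition.
#' @param n_pairs,n_pd Repeat counts; defaults from the phantom spec.
#' @param seed Integer seed for the acquisition noise.
#' @return An [asl_acquisition()] object.
#' @export
simulate_acquisition <- function(phantom, hct, params = sequence_params(),
                                 noise_sd = phantom$spec$noise_sd,
                                 n_pairs = phantom$spec$n_pairs,
                                 n_pd = phantom$spec$n_pd,
                                 seed = 1L) {
  spec <- phantom$spec
  if (identical(hct, "fixed")) hct <- params$hct_reference
  t1 <- t1_blood_from_hct(hct)
  if (noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  d <- dim(phantom$true_cbf)
  nz <- d[3]
  water <- phantom$pv$pv_gm + phantom$pv$pv_wm + phantom$pv$pv_csf
  pd_true <- spec$pd_level * water
  # expected labelled magnetisation, slice by slice (later slices decay more)
  dm <- array(0, d)
  for (z in seq_len(nz)) {
    f <- calibration_factor(params, t1,
                            pld_override = slice_effective_pld(params, z - 1L))
    dm[, , z] <- pd_true[, , z] * phantom$true_cbf[, , z] / f
  }
  static <- spec$bs_scale * pd_true
  sd_abs <- noise_sd * spec$pd_level
  set.seed(seed)
  noisy <- function(base, nrep) {
    out <- array(base, dim = c(d, nrep))
    if (sd_abs > 0)
      out <- out + array(stats::rnorm(length(out), 0, sd_abs), dim = dim(out))
    out
  }
  asl_acquisition(control_stack = noisy(static + dm / 2, n_pairs),
                  label_stack = noisy(static - dm / 2, n_pairs),
                  pd_stack = noisy(pd_true, n_pd),
                  grid = phantom$grid)
}
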