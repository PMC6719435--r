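#' Tissue partial-volume maps
#'
#' Voxelwise grey-matter, white-matter and CSF fractions on a grid. Each
#' fraction lies in [0, 1] and their sum must not exceed 1 (up to a small
#' tolerance); the remainder is background.
#'
#' @param pv_gm,pv_wm,pv_csf 3-D arrays of tissue fractions.
#' @param grid An [asl_grid()] descriptor.
#' @param tol Tolerance on the sum constraint.
#' @return An object of class `pv_maps`.
#' @export
pv_maps <- function(pv_gm, pv_wm, pv_csf = array(0, dim(pv_gm)),
                    grid = asl_grid(dim(pv_gm)), tol = 1e-6) {
  d <- dim(pv_gm)
  if (is.null(d) || length(d) != 3L)
    stop("partial-volume maps must be 3-D arrays", call. = FALSE)
  if (!identical(d, dim(pv_wm)) || !identical(d, dim(pv_csf)))
    stop("partial-volume maps must share one grid", call. = FALSE)
  rng <- range(pv_gm, pv_wm, pv_csf)
  if (rng[1] < -tol || rng[2] > 1 + tol)
    stop("tissue fractions must lie in [0, 1]", call. = FALSE)
  if (max(pv_gm + pv_wm + pv_csf) > 1 + tol)
    stop("tissue fractions must sum to <= 1 voxelwise", call. = FALSE)
  if (!identical(as.integer(grid$dim), as.integer(d)))
    stop("grid dimensions do not match the maps", call. = FALSE)
  structure(list(pv_gm = pv_gm, pv_wm = pv_wm, pv_csf = pv_csf, grid = grid),
            class = "pv_maps")
}

# Separable 1-D Gaussian smoothing along one array axis with reflecting
# boundaries; sigma in voxels of the axis. Kernel is normalised, so a
# constant field is a fixed point.
smooth_axis <- function(x, sigma, axis) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  d <- dim(x)
  n <- d[axis]
  idx <- outer(seq_len(n), (-half):half, `+`)
  idx[idx < 1L] <- 1L - idx[idx < 1L]          # reflect low edge
  idx[idx > n] <- 2L * n - idx[idx > n]        # reflect high edge
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dim(xp) <- c(n, prod(d[-axis]))
  out <- matrix(0, n, ncol(xp))
  for (j in seq_along(k)) out <- out + k[j] * xp[idx[, j], , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Block-average a high-resolution array into a coarser grid by integer
# factors. Exact mean over each block, so tissue mass is conserved.
block_average <- function(x, factors) {
  d <- dim(x)
  if (any(d %% factors != 0))
    stop("high-resolution grid is not an integer multiple of the target grid",
         call. = FALSE)
  dt <- d %/% factors
  a <- array(x, dim = c(factors[1], dt[1], factors[2], dt[2],
                        factors[3], dt[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dim = dt)
}

#' Resample partial-volume maps to the ASL grid through the point-spread
#' function
#'
#' High-resolution tissue segmentations are carried to the coarse ASL grid
#' in two steps: smoothing with the declared acquisition point-spread
#' function (Gaussian in-plane, delta through-plane by default), then exact
#' box-averaging into each target voxel. This accounts for the information
#' loss of down-sampling rather than naive decimation. Fractions remain in
#' [0, 1] and their sum is conserved (both operations are convex averages).
#'
#' @param pv_highres A [pv_maps()] object on the high-resolution grid.
#' @param target_grid An [asl_grid()] whose extent matches the source
#'   (dimensions must divide the source dimensions integrally).
#' @param psf_fwhm_mm In-plane PSF full width at half maximum in mm;
#'   default one target voxel. Use 0 for box-averaging only.
#' @return A [pv_maps()] object on `target_grid`.
#' @export
resample_pv_with_psf <- function(pv_highres, target_grid,
                                 psf_fwhm_mm = target_grid$pixdim[1]) {
  stopifnot(inherits(pv_highres, "pv_maps"), inherits(target_grid, "asl_grid"))
  src <- pv_highres$grid
  factors <- src$dim %/% target_grid$dim
  if (any(target_grid$dim > src$dim) ||
      any(src$dim != factors * target_grid$dim))
    stop("target grid must be coarser than the source by integer factors",
         call. = FALSE)
  extent_src <- src$dim * src$pixdim
  extent_tgt <- target_grid$dim * target_grid$pixdim
  if (max(abs(extent_src - extent_tgt)) > 1e-3)
    stop("incompatible affines: source and target grids cover different extents",
         call. = FALSE)
  sigma_vox <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / src$pixdim[1:2]
  one <- function(x) {
    y <- smooth_axis(smooth_axis(x, sigma_vox[1], 1L), sigma_vox[2], 2L)
    pmin(pmax(block_average(y, factors), 0), 1)
  }
  pv_maps(one(pv_highres$pv_gm), one(pv_highres$pv_wm),
          one(pv_highres$pv_csf), grid = target_grid)
}

#' Partial-volume correction by local linear regression
#'
#' Unmixes grey- and white-matter perfusion from voxels containing several
#' tissues. For every voxel, the perfusion values in a surrounding kernel
#' neighbourhood are regressed on the local GM and WM fractions
#' (`map ~ pv_gm * m_gm + pv_wm * m_wm`, no intercept); CSF is modelled as
#' non-perfused and therefore excluded from the design. The least-squares
#' solutions `m_gm`, `m_wm` are the tissue-specific perfusion estimates at
#' that voxel. Voxels whose local design matrix is ill-conditioned (nearly
#' collinear or empty tissue fractions) are masked invalid rather than
#' returned as zero.
#'
#' @param cbf_map 3-D perfusion array (may contain `NA` for invalid voxels).
#' @param pv A [pv_maps()] object on the same grid.
#' @param kernel Odd integer window sizes `(kx, ky, kz)`; default
#'   `c(5, 5, 1)`, in-plane only, respecting thick 2-D slices.
#' @param cond_max Condition-number cutoff for the local normal equations.
#' @return An object of class `pvc_result` with `gm_cbf_map`, `wm_cbf_map`,
#'   a logical `valid` mask and the kernel descriptor.
#' @export
pvc_linear_regression <- function(cbf_map, pv, kernel = c(5, 5, 1),
                                  cond_max = 1e6) {
  stopifnot(inherits(pv, "pv_maps"))
  d <- dim(cbf_map)
  if (!identical(d, dim(pv$pv_gm)))
    stop("perfusion map and partial-volume maps must share one grid",
         call. = FALSE)
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel < 1L) || any(kernel %% 2L == 0L))
    stop("kernel must be three odd window sizes", call. = FALSE)
  if (any(kernel > d))
    stop("kernel does not fit inside the volume", call. = FALSE)
  half <- kernel %/% 2L
  gm <- array(NA_real_, d)
  wm <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    zr <- max(1L, z - half[3]):min(d[3], z + half[3])
    for (y in seq_len(d[2])) {
      yr <- max(1L, y - half[2]):min(d[2], y + half[2])
      for (x in seq_len(d[1])) {
        xr <- max(1L, x - half[1]):min(d[1], x + half[1])
        yv <- cbf_map[xr, yr, zr]
        ok <- is.finite(yv)
        if (sum(ok) < 2L) next
        A <- cbind(gm = as.vector(pv$pv_gm[xr, yr, zr])[ok],
                   wm = as.vector(pv$pv_wm[xr, yr, zr])[ok])
        yv <- yv[ok]
        ngm <- sum(A[, 1]^2)
        nwm <- sum(A[, 2]^2)
        tiny <- 1e-12
        if (ngm <= tiny && nwm <= tiny)
          next                          # all-zero tissue: invalid, not zero
        if (ngm > tiny && nwm > tiny) {
          ata <- crossprod(A)
          ev <- eigen(ata, symmetric = TRUE, only.values = TRUE)$values
          if (ev[2] <= 0 || sqrt(ev[1] / ev[2]) > cond_max)
            next                        # ill-conditioned design: invalid
          beta <- solve(ata, crossprod(A, yv))
          gm[x, y, z] <- beta[1]
          wm[x, y, z] <- beta[2]
        } else if (ngm > tiny) {
          # pure-GM neighbourhood: WM is undetermined there
          gm[x, y, z] <- sum(A[, 1] * yv) / ngm
        } else {
          wm[x, y, z] <- sum(A[, 2] * yv) / nwm
        }
        valid[x, y, z] <- TRUE
      }
    }
  }
  structure(list(gm_cbf_map = gm, wm_cbf_map = wm, valid = valid,
                 kernel = kernel, cond_max = cond_max),
            class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat(sprintf("PVC result: kernel %s, %d/%d voxels valid\n",
              paste(x$kernel, collapse = "x"), sum(x$valid),
              length(x$valid)))
  invisible(x)
}

#' Cortical grey-matter mean of a PVC perfusion map
#'
#' Mean of the PVC grey-matter perfusion over valid voxels whose GM fraction
#' meets a threshold — the cortical grey-matter summary reported per
#' subject.
#'
#' @param pvc A [pvc_linear_regression()] result.
#' @param pv_gm 3-D GM fraction array on the same grid.
#' @param threshold GM-fraction threshold in (0, 1], default 0.5.
#' @return A list with `mean_cbf` (mL/100 g/min) and `n_voxels`.
#' @export
cortical_gm_mean <- function(pvc, pv_gm, threshold = 0.5) {
  stopifnot(inherits(pvc, "pvc_result"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  mask <- pvc$valid & pv_gm >= threshold & is.finite(pvc$gm_cbf_map)
  if (!any(mask))
    stop(sprintf("empty cortical mask: no valid voxel has pv_gm >= %g",
                 threshold), call. = FALSE)
  list(mean_cbf = mean(pvc$gm_cbf_map[mask]), n_voxels = sum(mask))
}
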