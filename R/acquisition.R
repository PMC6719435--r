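#' ASL acquisition container
#'
#' Holds the repeated control, label and proton-density volumes of one
#' subject on a common grid. Stacks are 4-D arrays `(x, y, z, repeat)`;
#' a 3-D array is treated as a single repeat. Control and label stacks must
#' have the same number of repeats (they are acquired as pairs).
#'
#' @param control_stack,label_stack,pd_stack Numeric arrays, 3-D or 4-D.
#' @param grid A grid descriptor as returned by [asl_grid()].
#' @return An object of class `asl_acquisition`.
#' @export
asl_acquisition <- function(control_stack, label_stack, pd_stack,
                            grid = asl_grid(dim(control_stack)[1:3])) {
  as4d <- function(x, nm) {
    if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", nm), call. = FALSE)
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) != 4L)
      stop(sprintf("'%s' must be a 3-D or 4-D array", nm), call. = FALSE)
    x
  }
  control_stack <- as4d(control_stack, "control_stack")
  label_stack <- as4d(label_stack, "label_stack")
  pd_stack <- as4d(pd_stack, "pd_stack")
  d <- dim(control_stack)[1:3]
  if (!identical(d, dim(label_stack)[1:3]) || !identical(d, dim(pd_stack)[1:3]))
    stop("control, label and PD stacks must share one grid", call. = FALSE)
  if (dim(control_stack)[4] != dim(label_stack)[4])
    stop("control and label stacks must have equal repeat counts",
         call. = FALSE)
  if (!identical(as.integer(grid$dim), as.integer(d)))
    stop("grid dimensions do not match the volume dimensions", call. = FALSE)
  structure(list(control_stack = control_stack, label_stack = label_stack,
                 pd_stack = pd_stack, grid = grid),
            class = "asl_acquisition")
}

#' Voxel grid descriptor
#'
#' @param dim Integer length-3 array dimensions.
#' @param pixdim Voxel size in mm, length 3.
#' @param origin World coordinates of voxel (0, 0, 0), length 3.
#' @return A list of class `asl_grid`. Voxel indices are 0-based; world
#'   coordinates are `origin + index * pixdim` (axis-aligned affine).
#' @export
asl_grid <- function(dim, pixdim = c(3.75, 3.75, 6), origin = c(0, 0, 0)) {
  stopifnot(length(dim) == 3L, length(pixdim) == 3L, all(pixdim > 0))
  structure(list(dim = as.integer(dim), pixdim = as.numeric(pixdim),
                 origin = as.numeric(origin)), class = "asl_grid")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    max(abs(a$pixdim - b$pixdim)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' @export
print.asl_acquisition <- function(x, ...) {
  cat(sprintf("ASL acquisition: %s grid, %d control/label pairs, %d PD repeats\n",
              paste(x$grid$dim, collapse = "x"),
              dim(x$control_stack)[4], dim(x$pd_stack)[4]))
  invisible(x)
}

#' Average repeated volumes
#'
#' Voxelwise arithmetic mean over the repeat dimension of the control, label
#' and proton-density stacks, the first processing step of quantification
#' (the study protocol averages 35 control/label pairs and the PD repeats).
#'
#' @param acq An [asl_acquisition()] object.
#' @return A list with 3-D arrays `mean_control`, `mean_label`, `mean_pd`
#'   and the repeat counts `n_pairs`, `n_pd`.
#' @export
average_repeats <- function(acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  m <- function(stack) {
    out <- rowMeans(stack, dims = 3L)
    dim(out) <- dim(stack)[1:3]
    out
  }
  list(mean_control = m(acq$control_stack),
       mean_label = m(acq$label_stack),
       mean_pd = m(acq$pd_stack),
       n_pairs = dim(acq$control_stack)[4],
       n_pd = dim(acq$pd_stack)[4])
}
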