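#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (plain or gzipped) into a numeric array tagged with
#' an [asl_grid()] descriptor taken from the header's voxel dimensions.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (array) and `grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  pix <- RNifti::pixdim(img)
  d <- dim(data)
  grid <- asl_grid(d[1:3], pixdim = pix[1:3])
  list(data = data, grid = grid)
}

#' Write a volume or perfusion map as NIfTI
#'
#' @param x A numeric array, or a [perfusion_map()] (its `NA` invalid
#'   voxels are stored as NaN).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid An [asl_grid()] descriptor (taken from `x` when it is a
#'   perfusion map).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "perfusion_map")) {
    grid <- x$grid
    x <- x$cbf
  }
  if (is.null(grid)) grid <- asl_grid(dim(x)[1:3])
  img <- RNifti::asNifti(x, internal = FALSE)
  RNifti::pixdim(img) <- rep_len(grid$pixdim, length(dim(x)))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a subject table
#'
#' Reads and validates the per-subject CSV. Mandatory columns: `id`, `sex`
#' (`M`/`F`), `ethnicity` (`white_european`, `south_asian`,
#' `african_caribbean`) and `hct`. Haematocrit is accepted either as a
#' percent (values > 1, e.g. `39.5`) or a fraction (values <= 1) and is
#' stored as a fraction; mixing conventions within one file is rejected.
#' Row-level validation problems are aggregated into a single error.
#'
#' @param path CSV path.
#' @return A validated data frame with `hct` as a fraction.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # sex codes "F"/"T" must never be parsed as logicals
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sex = "character"))
  if (nrow(df) == 0) stop("empty cohort file: ", path, call. = FALSE)
  mandatory <- c("id", "sex", "ethnicity", "hct")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("cohort file lacks mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  probs <- character()
  if (!is.numeric(df$hct)) probs <- c(probs, "hct is not numeric")
  else {
    pct <- df$hct > 1
    if (any(pct) && !all(pct))
      probs <- c(probs,
                 "hct mixes percent (> 1) and fraction (<= 1) conventions")
    else if (all(pct)) df$hct <- df$hct / 100
  }
  bad_sex <- !df$sex %in% c("M", "F")
  if (any(bad_sex))
    probs <- c(probs, sprintf("row %d: unknown sex '%s'",
                              which(bad_sex), df$sex[bad_sex]))
  known_eth <- c("white_european", "south_asian", "african_caribbean")
  bad_eth <- !df$ethnicity %in% known_eth
  if (any(bad_eth))
    probs <- c(probs, sprintf("row %d: unknown ethnicity '%s'",
                              which(bad_eth), df$ethnicity[bad_eth]))
  if (is.numeric(df$hct)) {
    bad_hct <- df$hct < 0.25 | df$hct > 0.55
    if (any(bad_hct))
      probs <- c(probs, sprintf("row %d: hct %.3f outside [0.25, 0.55]",
                                which(bad_hct), df$hct[bad_hct]))
  }
  if (length(probs))
    stop("invalid cohort file:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  if ("diabetes" %in% names(df)) df$diabetes <- as.logical(df$diabetes)
  df
}

#' Write a subject table
#'
#' @param cohort Data frame as produced by [generate_cohort()] or
#'   augmented with CBF columns.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' Reads a YAML configuration with blocks `sequence`, `phantom`, `cohort`,
#' `pvc`, `stats` and top-level `seed`. Unknown top-level blocks or unknown
#' keys inside a block are rejected (they usually indicate a typo that
#' would otherwise silently fall back to a default).
#'
#' @param path YAML path, or `NULL` for an all-defaults configuration.
#' @return A list of class `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- list(
    sequence = names(formals(sequence_params)),
    phantom = names(formals(phantom_spec)),
    cohort = c("hct_diabetes_shift", "cbf_hct_slope", "seed"),
    pvc = c("kernel", "gm_threshold", "cond_max", "psf_fwhm_mm"),
    stats = c("bandwidth", "alpha"))
  extra <- setdiff(names(raw), c(names(known), "seed"))
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (blk in names(known)) {
    bad <- setdiff(names(raw[[blk]]), known[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  cfg <- list(
    sequence = do.call(sequence_params, raw$sequence %||% list()),
    phantom = do.call(phantom_spec, raw$phantom %||% list()),
    cohort = do.call(cohort_spec, {
      ca <- raw$cohort %||% list()
      ca$seed <- NULL
      c(ca, list(seed = seed))
    }),
    pvc = utils::modifyList(list(kernel = c(5, 5, 1), gm_threshold = 0.5,
                                 cond_max = 1e6, psf_fwhm_mm = NULL),
                            raw$pvc %||% list()),
    stats = utils::modifyList(list(bandwidth = "nrd0", alpha = 0.05),
                              raw$stats %||% list()),
    seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
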