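#' Sequence parameters for PCASL quantification
#'
#' Bundles the acquisition constants entering the simplified Buxton
#' single-compartment model: the blood/brain partition coefficient
#' \eqn{\lambda}, the post-labelling delay (PLD), the labelling duration
#' \eqn{\tau}, the labelling efficiency \eqn{\alpha}, and the reference
#' haematocrit from which the standard fixed blood T1 (1650 ms) derives.
#' Slice-timing settings describe a 2-D multi-slice readout in which later
#' slices see a longer effective PLD.
#'
#' @param lambda_partition Blood/brain water partition coefficient, mL/g.
#' @param pld Post-labelling delay, ms.
#' @param tau Labelling duration, ms.
#' @param alpha Labelling efficiency, fraction in (0, 1].
#' @param hct_reference Reference haematocrit as a fraction in (0, 1);
#'   0.435 corresponds to the standard blood T1 of 1650 ms.
#' @param n_slices Number of slices in the 2-D readout.
#' @param slice_duration Acquisition time per slice, ms; added cumulatively
#'   to the PLD of later slices when `slice_timing_enabled` is `TRUE`.
#' @param slice_timing_enabled Apply per-slice effective PLDs?
#'
#' @return An object of class `sequence_params`.
#' @examples
#' sp <- sequence_params()
#' sp$pld # 2000 ms
#' @export
sequence_params <- function(lambda_partition = 0.9,
                            pld = 2000,
                            tau = 1800,
                            alpha = 0.85,
                            hct_reference = 0.435,
                            n_slices = 20,
                            slice_duration = 40,
                            slice_timing_enabled = TRUE) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  lambda_partition <- num1(lambda_partition, "lambda_partition")
  pld <- num1(pld, "pld")
  tau <- num1(tau, "tau")
  alpha <- num1(alpha, "alpha")
  hct_reference <- num1(hct_reference, "hct_reference")
  slice_duration <- num1(slice_duration, "slice_duration")
  if (lambda_partition <= 0 || pld <= 0 || tau <= 0)
    stop("lambda_partition, pld and tau must be positive", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (hct_reference <= 0 || hct_reference >= 1)
    stop("hct_reference must be a fraction in (0, 1)", call. = FALSE)
  if (slice_duration < 0)
    stop("slice_duration must be non-negative", call. = FALSE)
  n_slices <- as.integer(num1(n_slices, "n_slices"))
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  structure(
    list(lambda_partition = lambda_partition, pld = pld, tau = tau,
         alpha = alpha, hct_reference = hct_reference, n_slices = n_slices,
         slice_duration = slice_duration,
         slice_timing_enabled = isTRUE(slice_timing_enabled)),
    class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat("PCASL sequence parameters\n")
  cat(sprintf("  lambda = %.3g mL/g, PLD = %g ms, tau = %g ms, alpha = %.3g\n",
              x$lambda_partition, x$pld, x$tau, x$alpha))
  cat(sprintf("  reference Hct = %.1f%%, %d slices, slice timing %s (%g ms/slice)\n",
              100 * x$hct_reference, x$n_slices,
              if (x$slice_timing_enabled) "on" else "off", x$slice_duration))
  invisible(x)
}

#' Effective post-labelling delay for a slice
#'
#' In a sequential 2-D readout every slice after the first is acquired later,
#' so the label has decayed for longer. With slice timing enabled the
#' effective PLD of slice `slice_index` (0-based) is
#' `pld + slice_index * slice_duration`; otherwise the nominal PLD is used
#' for all slices.
#'
#' @param params A [sequence_params()] object.
#' @param slice_index 0-based slice index (vectorised).
#' @return Effective PLD in ms.
#' @examples
#' slice_effective_pld(sequence_params(), 10) # 2400
#' @export
slice_effective_pld <- function(params, slice_index) {
  stopifnot(inherits(params, "sequence_params"))
  if (any(slice_index < 0 | slice_index >= params$n_slices))
    stop(sprintf("slice_index must lie in [0, %d)", params$n_slices),
         call. = FALSE)
  if (!params$slice_timing_enabled)
    return(rep(params$pld, length(slice_index)))
  params$pld + slice_index * params$slice_duration
}
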