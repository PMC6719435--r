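#' Blood T1 from haematocrit
#'
#' Longitudinal relaxation time of arterial blood at 3 T as a function of
#' haematocrit, `T1 = 1/(0.52 * Hct + 0.38)` seconds with Hct a fraction.
#' At the reference haematocrit of 43.5% this yields the standard 1650 ms.
#' T1 decreases monotonically with Hct (more red cells, faster relaxation).
#'
#' Haematocrit must be supplied as a fraction; a value outside the admissible
#' range is rejected with a message naming the range, which in practice
#' catches percent values passed unconverted (e.g. 43.5 instead of 0.435).
#'
#' @param hct Haematocrit as a fraction (vectorised).
#' @param admissible Numeric length-2 admissible Hct range, default
#'   `c(0.25, 0.55)`.
#' @return An object of class `blood_t1` with fields `t1_seconds` and `hct`.
#' @examples
#' t1_blood_from_hct(0.435)$t1_seconds # 1.6496 s, i.e. ~1650 ms
#' @export
t1_blood_from_hct <- function(hct, admissible = c(0.25, 0.55)) {
  if (!is.numeric(hct) || length(hct) < 1L || any(!is.finite(hct)))
    stop("'hct' must be finite numeric", call. = FALSE)
  if (any(hct < admissible[1] | hct > admissible[2]))
    stop(sprintf(
      paste0("haematocrit %s outside the admissible range [%.2f, %.2f]; ",
             "Hct must be a fraction, not a percent (43.5%% -> 0.435)"),
      paste(format(hct[hct < admissible[1] | hct > admissible[2]]),
            collapse = ", "),
      admissible[1], admissible[2]), call. = FALSE)
  blood_t1(1 / (0.52 * hct + 0.38), hct = hct)
}

#' Construct a blood T1 value directly
#'
#' @param t1_seconds Blood T1 in seconds; must lie in (1.0, 2.5).
#' @param hct Optional haematocrit fraction the value derives from (`NA` for
#'   the fixed reference model).
#' @return An object of class `blood_t1`.
#' @export
blood_t1 <- function(t1_seconds, hct = NA_real_) {
  if (!is.numeric(t1_seconds) || any(!is.finite(t1_seconds)))
    stop("'t1_seconds' must be finite numeric", call. = FALSE)
  if (any(t1_seconds <= 1.0 | t1_seconds >= 2.5))
    stop("blood T1 must lie in (1.0, 2.5) s over the physiological Hct range",
         call. = FALSE)
  structure(list(t1_seconds = t1_seconds, hct = hct), class = "blood_t1")
}

#' @export
print.blood_t1 <- function(x, ...) {
  cat(sprintf("blood T1: %s ms%s\n",
              paste(format(round(1000 * x$t1_seconds, 1)), collapse = ", "),
              if (all(is.na(x$hct))) " (fixed reference)" else
                sprintf(" (Hct %s%%)",
                        paste(format(100 * x$hct), collapse = ", "))))
  invisible(x)
}

#' Calibration factor of the simplified Buxton model
#'
#' The scalar prefactor of the single-compartment PCASL quantification
#' \deqn{CBF = \frac{6000\,\lambda\, e^{PLD/T1}}{2\,\alpha\, T1\,
#'   (1 - e^{-\tau/T1})} \cdot \frac{SC - SL}{S_{PD}}}
#' isolated for reuse: `cbf = calibration_factor(params, t1) * (SC-SL)/SPD`
#' in mL/100 g/min. T1 is in seconds; PLD and \eqn{\tau} are converted from
#' ms internally. `pld_override` allows a per-slice effective PLD (ms).
#'
#' @param params A [sequence_params()] object.
#' @param t1 A `blood_t1` object (or numeric seconds).
#' @param pld_override Optional effective PLD in ms replacing `params$pld`.
#' @return The dimensionless-to-CBF scaling factor (numeric).
#' @examples
#' calibration_factor(sequence_params(), t1_blood_from_hct(0.435)) # ~9746
#' @export
calibration_factor <- function(params, t1, pld_override = NULL) {
  stopifnot(inherits(params, "sequence_params"))
  t1s <- if (inherits(t1, "blood_t1")) t1$t1_seconds else t1
  if (!is.numeric(t1s) || any(!is.finite(t1s)) || any(t1s <= 0))
    stop("invalid blood T1", call. = FALSE)
  pld_s <- (if (is.null(pld_override)) params$pld else pld_override) / 1000
  tau_s <- params$tau / 1000
  6000 * params$lambda_partition * exp(pld_s / t1s) /
    (2 * params$alpha * t1s * (1 - exp(-tau_s / t1s)))
}

#' Haematocrit correction ratio
#'
#' Ratio of CBF quantified with a subject-specific Hct-derived blood T1 to
#' CBF quantified with the fixed reference T1, for the same acquired signal.
#' Because the signal cancels, the ratio is a deterministic function of Hct
#' and the sequence parameters: it equals 1 at the reference haematocrit and
#' increases strictly with Hct, so subjects with Hct below 43.5% have their
#' CBF overestimated by the fixed model.
#'
#' @param hct Haematocrit fraction (vectorised).
#' @param params A [sequence_params()] object.
#' @param pld_override Optional effective PLD in ms.
#' @return `CBF_Hct / CBF_fixed`, dimensionless.
#' @examples
#' hct_correction_ratio(0.435) # exactly 1
#' hct_correction_ratio(0.406) # ~0.96: fixed model overestimates by ~4%
#' @export
hct_correction_ratio <- function(hct, params = sequence_params(),
                                 pld_override = NULL) {
  f_subj <- calibration_factor(params, t1_blood_from_hct(hct), pld_override)
  f_ref <- calibration_factor(params, t1_blood_from_hct(params$hct_reference),
                              pld_override)
  f_subj / f_ref
}
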