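#' Default stratum table of the synthetic cohort
#'
#' Sex-by-ethnicity strata of a tri-ethnic elderly community cohort
#' (white European, South Asian, African Caribbean men and women), with
#' per-stratum counts, haematocrit means/SDs (percent), diabetes prevalence
#' and true cortical grey-matter CBF means/SDs (mL/100 g/min).
#'
#' @return A data frame, one row per stratum.
#' @export
default_strata <- function() {
  data.frame(
    ethnicity = rep(c("white_european", "south_asian", "african_caribbean"),
                    each = 2),
    sex = rep(c("M", "F"), 3),
    n = c(148L, 78L, 108L, 67L, 41L, 51L),
    hct_mean_pct = c(43.8, 40.6, 42.0, 38.8, 43.0, 38.8),
    hct_sd_pct = c(3.4, 3.0, 3.6, 3.1, 3.5, 2.4),
    diabetes_prev = c(0.17, 0.17, 0.37, 0.37, 0.32, 0.32),
    cbf_mean = c(51.1, 51.1, 48.4, 45.7, 47.4, 44.5),
    cbf_sd = c(7.7, 7.0, 7.3, 5.0, 6.4, 6.0),
    stringsAsFactors = FALSE)
}

#' Cohort specification
#'
#' Defines the strata and generative settings of a synthetic cohort. By
#' default the six sex-by-ethnicity strata of [default_strata()] are used,
#' haematocrit is drawn from stratum-specific truncated normals on
#' [0.25, 0.55], diabetics receive a mean-preserving haematocrit decrement
#' (the stratum mean is unchanged; diabetics sit `hct_diabetes_shift`
#' percentage points below non-diabetics), and true CBF is coupled to
#' haematocrit with slope `cbf_hct_slope` mL/100 g/min per haematocrit
#' percentage point around the stratum mean.
#'
#' @param strata Data frame with columns `ethnicity`, `sex`, `n`,
#'   `hct_mean_pct`, `hct_sd_pct`, `diabetes_prev`, `cbf_mean`, `cbf_sd`.
#' @param hct_diabetes_shift Haematocrit decrement of diabetics versus
#'   non-diabetics, percentage points (positive = diabetics lower).
#' @param cbf_hct_slope True-CBF change per haematocrit percentage point.
#' @param hct_bounds Truncation bounds for haematocrit sampling, fraction.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(strata = default_strata(),
                        hct_diabetes_shift = 1.3,
                        cbf_hct_slope = -0.5,
                        hct_bounds = c(0.25, 0.55),
                        seed = 1L) {
  need <- c("ethnicity", "sex", "n", "hct_mean_pct", "hct_sd_pct",
            "diabetes_prev", "cbf_mean", "cbf_sd")
  miss <- setdiff(need, names(strata))
  if (length(miss))
    stop("strata table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(strata$n < 0)) stop("stratum counts must be >= 0", call. = FALSE)
  if (sum(strata$n) == 0) stop("cohort has zero subjects", call. = FALSE)
  if (any(strata$hct_sd_pct <= 0) || any(strata$cbf_sd <= 0))
    stop("stratum SDs must be positive", call. = FALSE)
  structure(list(strata = strata, hct_diabetes_shift = hct_diabetes_shift,
                 cbf_hct_slope = cbf_hct_slope, hct_bounds = hct_bounds,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-normal draws by redraw-on-violation.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad]
                           else mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject table reproducing the stratum structure of the
#' specification: haematocrit from stratum truncated normals with the
#' mean-preserving diabetes decrement, diabetes status from stratum
#' prevalence, demographics and blood lipids from published elderly-cohort
#' summaries, LDL from the Friedewald relation, and a latent true cortical
#' GM perfusion per subject coupled to haematocrit. Deterministic given the
#' spec's seed.
#'
#' @param spec A [cohort_spec()] object.
#' @return A data frame (one row per subject) with columns `id`, `sex`,
#'   `ethnicity`, `age`, `hct` (fraction), `diabetes`, `bmi`, `total_chol`,
#'   `hdl`, `triglycerides`, `ldl`, `map_bp`, `hba1c`, `cbf_true`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  lo <- 100 * spec$hct_bounds[1]
  hi <- 100 * spec$hct_bounds[2]
  # demographic/lipid summaries (means, SDs) by sex or ethnicity
  age_m <- c(M = 72.9, F = 69.7); age_s <- c(M = 5.2, F = 6.4)
  bmi_m <- c(white_european = 27.5, south_asian = 26.4,
             african_caribbean = 29.6)
  hba1c_m <- c(white_european = 39.2, south_asian = 43.9,
               african_caribbean = 43.6)
  chol_m <- c(white_european = 4.8, south_asian = 4.5,
              african_caribbean = 4.8)
  hdl_m <- c(white_european = 1.6, south_asian = 1.5,
             african_caribbean = 1.8)
  rows <- lapply(seq_len(nrow(spec$strata)), function(i) {
    st <- spec$strata[i, ]
    n <- st$n
    if (n == 0L) return(NULL)
    diabetes <- stats::runif(n) < st$diabetes_prev
    # mean-preserving split: stratum mean stays at hct_mean_pct while
    # diabetics sit hct_diabetes_shift points below non-diabetics
    mu <- st$hct_mean_pct +
      ifelse(diabetes, -(1 - st$diabetes_prev), st$diabetes_prev) *
      spec$hct_diabetes_shift
    hct_pct <- rnorm_trunc(n, mu, st$hct_sd_pct, lo, hi)
    resid_sd <- sqrt(max(st$cbf_sd^2 -
                           (spec$cbf_hct_slope * st$hct_sd_pct)^2,
                         (0.5 * st$cbf_sd)^2))
    cbf_true <- st$cbf_mean +
      spec$cbf_hct_slope * (hct_pct - st$hct_mean_pct) +
      stats::rnorm(n, 0, resid_sd)
    tg <- rnorm_trunc(n, 1.4, 0.6, 0.3, 8)
    tc <- rnorm_trunc(n, chol_m[[st$ethnicity]], 1.0, 2, 10)
    hdl <- rnorm_trunc(n, hdl_m[[st$ethnicity]], 0.4, 0.5, 4)
    data.frame(
      sex = st$sex, ethnicity = st$ethnicity,
      age = round(rnorm_trunc(n, age_m[[st$sex]], age_s[[st$sex]], 55, 90), 1),
      hct = hct_pct / 100,
      diabetes = diabetes,
      bmi = round(rnorm_trunc(n, bmi_m[[st$ethnicity]], 4.2, 16, 50), 1),
      total_chol = round(tc, 2), hdl = round(hdl, 2),
      triglycerides = round(tg, 2),
      map_bp = round(rnorm_trunc(n, 97.0, 10.0, 60, 140), 1),
      hba1c = round(rnorm_trunc(n, hba1c_m[[st$ethnicity]] +
                                  ifelse(diabetes, 10, -2), 6, 20, 120), 1),
      cbf_true = cbf_true,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ldl <- ldl_friedewald(out$total_chol, out$hdl, out$triglycerides)
  out <- cbind(id = sprintf("S%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out[, c("id", "sex", "ethnicity", "age", "hct", "diabetes", "bmi",
          "total_chol", "hdl", "triglycerides", "ldl", "map_bp", "hba1c",
          "cbf_true")]
}

#' LDL cholesterol by the Friedewald relation
#'
#' `LDL = total cholesterol - HDL - triglycerides / 2.2` (all mmol/L),
#' valid only for triglycerides below 4.52 mmol/L; above that bound the
#' estimate is unreliable and `NA` is returned (flagged missing).
#'
#' @param total_chol,hdl,triglycerides mmol/L (vectorised).
#' @return LDL cholesterol, mmol/L; `NA` where triglycerides >= 4.52.
#' @examples
#' ldl_friedewald(4.7, 1.6, 1.1) # 2.6
#' @export
ldl_friedewald <- function(total_chol, hdl, triglycerides) {
  ldl <- total_chol - hdl - triglycerides / 2.2
  ldl[triglycerides >= 4.52] <- NA_real_
  ldl
}
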