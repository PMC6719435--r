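#' Cohen's d for a paired model contrast
#'
#' Standardised effect size used for the fixed-vs-individualised model
#' comparison: the absolute mean paired difference divided by the pooled SD
#' of the two measurement sets, `|mean(b - a)| / sqrt((sd_a^2 + sd_b^2)/2)`.
#' Note this is the pooled-SD-of-the-two-measures form, not the
#' SD-of-differences form: paired CBF values from the two quantification
#' models are extremely correlated, so the SD-of-differences form would
#' yield effect sizes an order of magnitude larger than those conventionally
#' reported for this contrast.
#'
#' @param mean_diff Mean paired difference (sign ignored).
#' @param sd_a,sd_b Standard deviations of the two measurement sets.
#' @return Cohen's d (non-negative).
#' @examples
#' cohens_d(1.8, 8.3, 7.5) # 0.23
#' @export
cohens_d <- function(mean_diff, sd_a, sd_b) {
  abs(mean_diff) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Paired comparison of two CBF quantification models
#'
#' Paired t test of per-subject CBF under the fixed-reference and
#' Hct-individualised models, with the 95% CI of the mean difference,
#' Cohen's d (pooled-SD form, see [cohens_d()]) and the mean per-subject
#' percent difference `100 * (hct - fixed) / fixed`.
#'
#' @param cbf_fixed,cbf_hct Equal-length per-subject CBF vectors,
#'   mL/100 g/min.
#' @param conf_level Confidence level for the CI of the mean difference.
#' @return An object of class `comparison_result`: a list with `n`,
#'   `mean_fixed`, `sd_fixed`, `mean_hct`, `sd_hct`, `mean_diff`,
#'   `ci_lower`, `ci_upper`, `t_statistic`, `p_value`, `cohens_d`,
#'   `diff_sign`, `mean_pct_diff`. The difference is `hct - fixed`.
#' @export
paired_comparison <- function(cbf_fixed, cbf_hct, conf_level = 0.95) {
  n <- length(cbf_fixed)
  if (n != length(cbf_hct))
    stop("paired vectors must have equal length", call. = FALSE)
  if (n < 2L) stop("paired comparison needs n >= 2", call. = FALSE)
  diffs <- cbf_hct - cbf_fixed
  md <- mean(diffs)
  if (stats::sd(diffs) == 0) {
    # degenerate: identical differences everywhere (e.g. both models agree)
    tt <- list(statistic = c(t = 0), p.value = 1, conf.int = c(md, md))
    if (md != 0)
      tt <- list(statistic = c(t = sign(md) * Inf), p.value = 0,
                 conf.int = c(md, md))
  } else {
    tt <- stats::t.test(cbf_hct, cbf_fixed, paired = TRUE,
                        conf.level = conf_level)
  }
  structure(list(
    n = n,
    mean_fixed = mean(cbf_fixed), sd_fixed = stats::sd(cbf_fixed),
    mean_hct = mean(cbf_hct), sd_hct = stats::sd(cbf_hct),
    mean_diff = md,
    ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    cohens_d = cohens_d(md, stats::sd(cbf_fixed), stats::sd(cbf_hct)),
    diff_sign = sign(md),
    mean_pct_diff = mean(100 * (cbf_hct - cbf_fixed) / cbf_fixed)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    paste0("paired model contrast (n = %d)\n",
           "  fixed %.1f +/- %.1f, hct %.1f +/- %.1f mL/100g/min\n",
           "  difference %.2f (%.2f, %.2f), %s%% | t = %.2f, p %s, d = %.2f\n"),
    x$n, x$mean_fixed, x$sd_fixed, x$mean_hct, x$sd_hct,
    x$mean_diff, x$ci_lower, x$ci_upper, format(round(x$mean_pct_diff, 1)),
    x$t_statistic, format_p(x$p_value), x$cohens_d))
  invisible(x)
}

# display convention mirroring clinical tables
format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", paste0("= ", format(round(p, 3))))
}

#' Per-stratum percent difference between CBF models
#'
#' Two definitions of the mean percent difference are reported side by
#' side: the primary per-subject mean of `100 * (hct - fixed)/fixed` (which
#' is signal-independent, each subject's percentage being a deterministic
#' function of haematocrit) and the cohort-level ratio of means
#' `100 * (mean_hct - mean_fixed)/mean_fixed`. Subjects with a
#' non-positive fixed-model value cannot contribute a percentage and are
#' excluded with a warning.
#'
#' @param cohort Data frame with columns `cbf_fixed` and `cbf_hct` plus any
#'   grouping columns.
#' @param by Character vector of grouping columns; `NULL` for the whole
#'   cohort.
#' @return A data frame with one row per stratum: `n`, `pct_diff_subject`
#'   (primary) and `pct_diff_ratio` (secondary).
#' @export
percent_difference_summary <- function(cohort, by = NULL) {
  stopifnot(all(c("cbf_fixed", "cbf_hct") %in% names(cohort)))
  bad <- cohort$cbf_fixed <= 0
  if (any(bad)) {
    warning(sprintf("%d subject(s) with non-positive fixed-model CBF excluded",
                    sum(bad)), call. = FALSE)
    cohort <- cohort[!bad, , drop = FALSE]
  }
  one <- function(df) {
    data.frame(
      n = nrow(df),
      pct_diff_subject = mean(100 * (df$cbf_hct - df$cbf_fixed) /
                                df$cbf_fixed),
      pct_diff_ratio = 100 * (mean(df$cbf_hct) - mean(df$cbf_fixed)) /
        mean(df$cbf_fixed))
  }
  if (is.null(by)) return(one(cohort))
  parts <- split(cohort, cohort[by], drop = TRUE)
  out <- do.call(rbind, lapply(parts, one))
  key <- do.call(rbind, strsplit(names(parts), "\\."))
  colnames(key) <- by
  cbind(as.data.frame(key, stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Pearson correlation between haematocrit and CBF
#'
#' @param hct Haematocrit values (fraction or percent, used as given).
#' @param cbf CBF values, same length.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_hct_cbf <- function(hct, cbf) {
  n <- length(hct)
  if (n != length(cbf)) stop("inputs must have equal length", call. = FALSE)
  if (n < 3L) stop("correlation needs n >= 3", call. = FALSE)
  if (stats::sd(hct) == 0 || stats::sd(cbf) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(hct, cbf, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Two-way ANOVA with Fisher's LSD follow-up
#'
#' Two-way analysis of variance of a response on two crossed factors (sex
#' and ethnicity in the cohort analysis) using Type II sums of squares,
#' appropriate for the unbalanced cell counts of an observational cohort.
#' If (and only if) a factor's ANOVA p-value falls below `alpha`,
#' individual group-wise comparisons against that factor's reference level
#' are performed with Fisher's least significant difference test: pairwise
#' t statistics using the pooled residual mean square of the full model,
#' with no further multiplicity correction.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced); the first level of each is
#'   the reference.
#' @param alpha Significance gate for performing LSD comparisons.
#' @return A list with `anova` (data frame of F tests for both main
#'   effects and the interaction) and `lsd` (data frame of reference-level
#'   comparisons, or `NULL` when not performed).
#' @export
two_way_anova_lsd <- function(values, factor_a, factor_b, alpha = 0.05) {
  factor_a <- as.factor(factor_a)
  factor_b <- as.factor(factor_b)
  if (nlevels(droplevels(factor_a)) < 2L ||
      nlevels(droplevels(factor_b)) < 2L)
    stop("each factor needs >= 2 observed levels", call. = FALSE)
  tab <- table(factor_a, factor_b)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s x %s",
                 levels(factor_a)[empty[1]], levels(factor_b)[empty[2]]),
         call. = FALSE)
  }
  df <- data.frame(y = values, a = factor_a, b = factor_b)
  fit <- stats::lm(y ~ a * b, data = df)
  a2 <- car::Anova(fit, type = 2)
  an <- data.frame(term = c("factor_a", "factor_b", "interaction"),
                   sum_sq = a2$`Sum Sq`[1:3], df = a2$Df[1:3],
                   f_value = a2$`F value`[1:3], p_value = a2$`Pr(>F)`[1:3])
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  lsd_for <- function(f, other) {
    ref <- levels(f)[1]
    do.call(rbind, lapply(levels(f)[-1], function(lv) {
      i <- f == lv; j <- f == ref
      se <- sqrt(mse * (1 / sum(i) + 1 / sum(j)))
      tstat <- (mean(values[i]) - mean(values[j])) / se
      data.frame(comparison = paste(lv, "vs", ref),
                 mean_diff = mean(values[i]) - mean(values[j]),
                 t_value = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), fit$df.residual))
    }))
  }
  lsd <- NULL
  do_a <- is.finite(an$p_value[1]) && an$p_value[1] < alpha
  do_b <- is.finite(an$p_value[2]) && an$p_value[2] < alpha
  if (do_a || do_b)
    lsd <- rbind(if (do_a) cbind(factor = "factor_a", lsd_for(factor_a)),
                 if (do_b) cbind(factor = "factor_b", lsd_for(factor_b)))
  list(anova = an, lsd = lsd)
}

#' Adjusted linear model of CBF on haematocrit
#'
#' Ordinary least squares of CBF on haematocrit with optional adjustment
#' for confounders. Incomplete rows are dropped (listwise deletion) with
#' the count recorded; a rank-deficient design aborts with the names of the
#' collinear columns rather than silently aliasing them.
#'
#' @param cbf Response, mL/100 g/min.
#' @param hct Haematocrit (percent or fraction; coefficient is per unit of
#'   whatever is supplied).
#' @param covariates Optional data frame of confounders (e.g. age, mean
#'   arterial pressure, diabetes, HbA1c, LDL, HDL, BMI).
#' @param conf_level Confidence level for coefficient intervals.
#' @return A list with `coefficients` (data frame: estimate, CI bounds,
#'   p value), `n_used`, `n_dropped` and the underlying `lm` fit.
#' @export
linear_adjusted_model <- function(cbf, hct, covariates = NULL,
                                  conf_level = 0.95) {
  df <- data.frame(cbf = cbf, hct = hct)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(cbf))
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) <= ncol(df) + 1L)
    stop("too few complete cases for the requested model", call. = FALSE)
  fit <- stats::lm(cbf ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ci <- stats::confint(fit, level = conf_level)
  sm <- stats::summary.lm(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      p_value = sm[, 4], row.names = NULL)
  list(coefficients = coefs, n_used = nrow(df), n_dropped = n_dropped,
       fit = fit)
}

#' Kernel density estimate of a CBF distribution
#'
#' Gaussian-kernel density on an evaluation grid, used to compare the
#' sample frequency distributions of CBF under the two quantification
#' models. Bandwidth defaults to Silverman's rule of thumb.
#'
#' @param values Numeric sample, `NA` removed.
#' @param bandwidth Numeric bandwidth, or a rule name accepted by
#'   [stats::density()] (`"nrd0"` = Silverman's rule).
#' @param n_grid Number of evaluation points.
#' @return A data frame with columns `x` and `density`; the trapezoidal
#'   integral over the grid is 1 to within 1e-3.
#' @export
kernel_density <- function(values, bandwidth = "nrd0", n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("density needs n >= 2", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: bandwidth rules undefined", call. = FALSE)
  if (is.numeric(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  dn <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                       n = n_grid, cut = 4)
  data.frame(x = dn$x, density = dn$y)
}
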