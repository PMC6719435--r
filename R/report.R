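#' Stratified model-comparison report
#'
#' Builds the full table of paired fixed-vs-individualised model contrasts:
#' the whole cohort, by sex, by ethnicity (all/men/women within each), and
#' by diabetes status — one [paired_comparison()] per stratum, flattened to
#' a data frame.
#'
#' @param cohort Data frame with columns `cbf_fixed`, `cbf_hct`, `sex`,
#'   `ethnicity`, `diabetes`.
#' @return A data frame with one row per stratum: `stratum`, `n`, the model
#'   means/SDs, mean difference with CI, t, p, Cohen's d, and the mean
#'   per-subject percent difference.
#' @export
stratified_report <- function(cohort) {
  need <- c("cbf_fixed", "cbf_hct", "sex", "ethnicity", "diabetes")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  row_of <- function(label, df) {
    cr <- paired_comparison(df$cbf_fixed, df$cbf_hct)
    data.frame(stratum = label, n = cr$n,
               mean_fixed = cr$mean_fixed, sd_fixed = cr$sd_fixed,
               mean_hct = cr$mean_hct, sd_hct = cr$sd_hct,
               mean_diff = cr$mean_diff,
               ci_lower = cr$ci_lower, ci_upper = cr$ci_upper,
               mean_pct_diff = cr$mean_pct_diff,
               t_statistic = cr$t_statistic, p_value = cr$p_value,
               cohens_d = cr$cohens_d,
               stringsAsFactors = FALSE)
  }
  strata <- list(all = cohort,
                 men = cohort[cohort$sex == "M", ],
                 women = cohort[cohort$sex == "F", ])
  for (eth in unique(cohort$ethnicity)) {
    e <- cohort[cohort$ethnicity == eth, ]
    strata[[paste0(eth, "_all")]] <- e
    strata[[paste0(eth, "_men")]] <- e[e$sex == "M", ]
    strata[[paste0(eth, "_women")]] <- e[e$sex == "F", ]
  }
  strata$without_diabetes <- cohort[!cohort$diabetes, ]
  strata$with_diabetes <- cohort[cohort$diabetes, ]
  strata <- Filter(function(df) nrow(df) >= 2, strata)
  out <- do.call(rbind, Map(row_of, names(strata), strata))
  rownames(out) <- NULL
  out
}
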