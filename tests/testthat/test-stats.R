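test_that("the pooled-SD effect size reproduces published contrasts", {
  # definitional validation: d computed from each stratum's printed
  # means/SDs/differences agrees with the printed d (printed inputs are
  # rounded to 1 dp, which propagates to ~0.01 in d)
  pub <- published_contrasts()
  d_got <- cohens_d(pub$mean_diff, pub$sd_fixed, pub$sd_hct)
  expect_lt(max(abs(d_got - pub$d)), 0.015)
  # most rows agree to the printed 2 dp exactly
  expect_gte(sum(round(d_got, 2) == pub$d), 9)
  # spot values quoted in the text (absolute deviation)
  expect_lt(abs(cohens_d(1.8, 8.3, 7.5) - 0.23), 0.005)
  expect_lt(abs(cohens_d(2.7, 7.2, 6.8) - 0.38), 0.01)
})

test_that("paired comparison computes the full contrast summary", {
  set.seed(101)
  n <- 80
  fixed <- rnorm(n, 50, 7)
  r <- hct_correction_ratio(rnorm(n, 0.40, 0.03))
  hct_cbf <- fixed * r
  cr <- paired_comparison(fixed, hct_cbf)
  expect_equal(cr$n, n)
  expect_equal(cr$mean_diff, mean(hct_cbf - fixed), tolerance = 1e-12)
  # agrees with stats::t.test as the reference implementation
  tt <- t.test(hct_cbf, fixed, paired = TRUE)
  expect_equal(cr$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cr$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(c(cr$ci_lower, cr$ci_upper), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  # CI brackets the mean difference; d carries a separate sign field
  expect_true(cr$ci_lower <= cr$mean_diff && cr$mean_diff <= cr$ci_upper)
  expect_gte(cr$cohens_d, 0)
  expect_equal(cr$diff_sign, -1)
  # identical vectors: zero difference, d = 0, p = 1 by convention
  same <- paired_comparison(fixed, fixed)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_comparison(fixed, fixed[-1]), "equal length")
  expect_error(paired_comparison(1, 2), "n >= 2")
})

test_that("percent difference offers per-subject and ratio definitions", {
  df <- data.frame(cbf_fixed = c(50, 40), cbf_hct = c(45, 42),
                   sex = c("F", "M"))
  out <- percent_difference_summary(df)
  expect_equal(out$pct_diff_subject, mean(c(-10, 5)), tolerance = 1e-12)
  expect_equal(out$pct_diff_ratio, 100 * (87 - 90) / 90, tolerance = 1e-12)
  # single subject: both definitions coincide
  one <- percent_difference_summary(df[1, ])
  expect_equal(one$pct_diff_subject, one$pct_diff_ratio)
  # all subjects at the reference haematocrit: exactly zero
  ref <- data.frame(cbf_fixed = c(48, 52, 55), cbf_hct = c(48, 52, 55))
  expect_equal(percent_difference_summary(ref)$pct_diff_subject, 0)
  # grouping splits by stratum
  g <- percent_difference_summary(df, by = "sex")
  expect_equal(nrow(g), 2)
  expect_equal(g$pct_diff_subject[g$sex == "F"], -10)
  # non-positive fixed values are excluded with a warning
  bad <- rbind(df, data.frame(cbf_fixed = -1, cbf_hct = 2, sex = "F"))
  expect_warning(out2 <- percent_difference_summary(bad), "excluded")
  expect_equal(out2$n, 2)
})

test_that("Pearson correlation handles exact and null relationships", {
  hct <- seq(0.30, 0.50, length.out = 20)
  # exact negative linear relation
  res <- pearson_hct_cbf(hct, 100 - 80 * hct)
  expect_equal(res$r, -1, tolerance = 1e-12)
  # independent draws: near-zero correlation at large n
  set.seed(55)
  res0 <- pearson_hct_cbf(rnorm(4000), rnorm(4000))
  expect_lt(abs(res0$r), 0.05)
  expect_error(pearson_hct_cbf(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_hct_cbf(1:2, 1:2), "n >= 3")
})

test_that("haematocrit correction attenuates the Hct-CBF correlation", {
  co <- generate_cohort(cohort_spec(seed = 12))
  both <- quantify_signal_ratio(
    co$cbf_true / calibration_factor(sequence_params(),
                                     t1_blood_from_hct(co$hct)),
    co$hct)
  r_fixed <- pearson_hct_cbf(co$hct, both$cbf_fixed)
  r_hct <- pearson_hct_cbf(co$hct, both$cbf_hct)
  expect_lt(r_fixed$r, 0)
  expect_lt(abs(r_hct$r), abs(r_fixed$r))
})

test_that("two-way ANOVA F statistics match brute-force sums of squares", {
  # balanced 2x3 toy table: Type II equals the classical decomposition,
  # which the oracle computes from explicit group means
  y <- c(10, 12, 11, 13, 20, 22, 21, 23, 30, 32, 31, 33)
  a <- factor(rep(c("m", "f"), 6))
  b <- factor(rep(c("e1", "e2", "e3"), each = 4))
  out <- two_way_anova_lsd(y, a, b)
  grand <- mean(y)
  ss_a <- sum(tapply(y, a, length) * (tapply(y, a, mean) - grand)^2)
  ss_b <- sum(tapply(y, b, length) * (tapply(y, b, mean) - grand)^2)
  cell <- tapply(y, interaction(a, b), mean)
  ss_cells <- sum(2 * (cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - ave(y, interaction(a, b)))^2)
  f_a <- (ss_a / 1) / (ss_err / 6)
  f_b <- (ss_b / 2) / (ss_err / 6)
  f_ab <- (ss_ab / 2) / (ss_err / 6)
  expect_equal(out$anova$f_value, c(f_a, f_b, f_ab), tolerance = 1e-10)
  expect_equal(out$anova$df, c(1, 2, 2))
})

test_that("Fisher's LSD is gated on ANOVA significance", {
  # flat means, equal n: F ~ 0, no LSD performed
  set.seed(77)
  y <- rnorm(24, 50, 1)
  a <- factor(rep(c("m", "f"), 12))
  b <- factor(rep(c("e1", "e2", "e3"), each = 8))
  out <- two_way_anova_lsd(y, a, b)
  expect_true(all(out$anova$p_value > 0.05, na.rm = TRUE))
  expect_null(out$lsd)
  # a strong factor effect triggers reference-level comparisons
  y2 <- y + ifelse(b == "e3", 10, 0)
  out2 <- two_way_anova_lsd(y2, a, b)
  expect_lt(out2$anova$p_value[2], 0.05)
  expect_true(!is.null(out2$lsd))
  expect_true(all(grepl("vs e1", out2$lsd$comparison[out2$lsd$factor ==
                                                       "factor_b"])))
  # empty cells are named in the error
  a3 <- a; a3[b == "e3"] <- "f"
  expect_error(two_way_anova_lsd(y, droplevels(a3), b), "empty cell")
})

test_that("adjusted linear models recover known coefficients", {
  gen <- function(seed, n = 150) {
    set.seed(seed)
    hct <- rnorm(n, 41, 3.5)
    age <- rnorm(n, 71, 6)
    dia <- rbinom(n, 1, 0.3)
    cbf <- 80 - 0.6 * hct - 0.1 * age - 2 * dia + rnorm(n, 0, 4)
    data.frame(cbf, hct, age, dia)
  }
  covered <- vapply(1:30, function(s) {
    df <- gen(s)
    fit <- linear_adjusted_model(df$cbf, df$hct, df[c("age", "dia")])
    ci <- fit$coefficients[fit$coefficients$term == "hct", ]
    ci$ci_lower <= -0.6 && -0.6 <= ci$ci_upper
  }, logical(1))
  # nominal 95% coverage; binomial noise at 30 replicates allows dips
  expect_gte(mean(covered), 0.8)
  # no covariates: slope equals the simple regression of cbf on hct
  df <- gen(1)
  m0 <- linear_adjusted_model(df$cbf, df$hct)
  expect_equal(m0$coefficients$estimate[m0$coefficients$term == "hct"],
               unname(coef(lm(cbf ~ hct, df))["hct"]), tolerance = 1e-12)
  # rank deficiency names the offending column
  expect_error(linear_adjusted_model(df$cbf, df$hct,
                                     data.frame(age = df$age,
                                                zero = rep(0, nrow(df)))),
               "zero")
  # listwise deletion is logged
  df$age[1:5] <- NA
  m1 <- linear_adjusted_model(df$cbf, df$hct, df[c("age", "dia")])
  expect_equal(m1$n_dropped, 5)
  expect_equal(m1$n_used, nrow(df) - 5)
})

test_that("kernel density estimates are proper densities", {
  set.seed(88)
  x <- rnorm(1e4)
  kd <- kernel_density(x)
  expect_true(all(kd$density >= 0))
  integral <- sum(diff(kd$x) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # close to the standard normal pdf at this sample size
  expect_lt(max(abs(kd$density - dnorm(kd$x))), 0.02)
  # shift equivariance
  kd5 <- kernel_density(x + 5)
  expect_equal(kd5$x, kd$x + 5, tolerance = 1e-8)
  expect_equal(kd5$density, kd$density, tolerance = 1e-10)
  expect_error(kernel_density(rep(3, 10)), "zero variance")
  expect_error(kernel_density(x, bandwidth = -1), "positive")
})
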