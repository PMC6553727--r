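test_that("Bland-Altman statistics match hand arithmetic and the LOA identity", {
  # identical series
  expect_equal(as.numeric(bland_altman(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0, 0))
  # constant offset: bias 0.70, zero-width LOA
  x <- c(37.5, 38.1, 36.9)
  ba <- bland_altman(x, x - 0.70)
  expect_equal(ba$bias, 0.70)
  expect_equal(ba$loa_high - ba$loa_low, 0)
  # worked example: diffs {0.5, 1.0, 1.5}
  ba <- bland_altman(c(1.5, 2.0, 2.5), c(1.0, 1.0, 1.0))
  expect_equal(ba$bias, 1.0, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.5, tolerance = 1e-12)
  expect_equal(ba$loa_low, 1 - 1.96 * 0.5, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1 + 1.96 * 0.5, tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), class = "keratrace_domain_error")
  expect_error(bland_altman(c(1, NA), c(1, 2)), class = "keratrace_domain_error")
})

test_that("Pearson correlation matches hand computation and affine invariance", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  pe <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pe$r, 0.8, tolerance = 1e-12)
  # dual route: p from the t transform with n - 2 df
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(pe$p, 2 * pt(-tstat, df = 2), tolerance = 1e-12)
  # invariance to positive affine transforms
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(pearson(2.5 * x + 7, y)$r, pearson(x, y)$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), class = "keratrace_zero_variance")
})

test_that("repeated-measures ANOVA matches hand-computed within-subject sums of squares", {
  # 5 subjects x 3 methods worked matrix
  mat <- cbind(CHM = c(37.1, 38.0, 36.5, 37.8, 39.0),
               A   = c(37.9, 38.4, 37.3, 38.1, 39.8),
               B   = c(36.8, 37.5, 36.1, 37.2, 38.3))
  res <- repeated_measures_compare(mat, reference = "CHM")
  # independent oracle: textbook RM-ANOVA arithmetic
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_method <- n * sum((colMeans(mat) - grand)^2)
  ss_subject <- k * sum((rowMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_error <- ss_total - ss_method - ss_subject
  F_hand <- (ss_method / (k - 1)) / (ss_error / ((n - 1) * (k - 1)))
  p_hand <- stats::pf(F_hand, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  expect_equal(res$F, F_hand, tolerance = 1e-9)
  expect_equal(res$p, p_hand, tolerance = 1e-9)
  # pairwise contrasts: paired t vs reference, Bonferroni x2
  t_a <- t.test(mat[, "A"], mat[, "CHM"], paired = TRUE)
  expect_equal(res$pairwise$p_raw[res$pairwise$method == "A"], t_a$p.value,
               tolerance = 1e-12)
  expect_equal(res$pairwise$p_adjusted, pmin(1, res$pairwise$p_raw * 2),
               tolerance = 1e-15)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
})

test_that("degenerate repeated-measures inputs are handled with documented conventions", {
  base <- c(37.0, 37.5, 38.0, 36.5)
  # identical columns: F = 0, adjusted p = 1
  same <- cbind(CHM = base, A = base, B = base)
  res <- repeated_measures_compare(same, reference = "CHM")
  expect_equal(res$F, 0)
  expect_true(all(res$pairwise$p_adjusted == 1))
  # exact constant offset: epsilon-floored p, never exactly zero
  off <- cbind(CHM = base, A = base + 1.0)
  res2 <- repeated_measures_compare(off, reference = "CHM")
  expect_gt(res2$pairwise$p_raw, 0)
  expect_lt(res2$pairwise$p_raw, 1e-12)
  expect_error(repeated_measures_compare(cbind(a = c(1, NA, 3), b = 1:3)),
               class = "keratrace_domain_error")
  expect_error(repeated_measures_compare(same[1:2, ]),
               class = "keratrace_domain_error")
})

test_that("normality annotation is calibrated on normal and skewed samples", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rnorm(50))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- vapply(1:100, function(s) {
    set.seed(s); normality_check(rexp(100))$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(normality_check(rep(1, 10)), class = "keratrace_zero_variance")
  expect_error(normality_check(1:2), class = "keratrace_domain_error")
})

test_that("build_report produces the full method layout with exact LOA identities", {
  co <- generate_cohort(cohort_config(n = 12, seed = 31), keratometry = TRUE)
  tbl <- cohort_to_table(co)
  rep <- build_report(tbl)
  # 19 regular rows (CHM + 18 methods) + 2 modified rows
  expect_equal(nrow(rep$table2), 21)
  expect_equal(rep$table2$method[1], "CHM")
  expect_equal(rep$metadata$bonferroni_m, 20)
  expect_equal(rep$metadata$seed, 31)
  # LOA identity holds exactly for every comparison row
  cmp <- rep$table2[!is.na(rep$table2$bias), ]
  expect_equal(cmp$loa_low, cmp$bias - 1.96 * cmp$sd_diff, tolerance = 1e-9)
  expect_equal(cmp$loa_high, cmp$bias + 1.96 * cmp$sd_diff, tolerance = 1e-9)
  # table1: 4 variants x 8 diameters
  expect_equal(nrow(rep$table1), 32)
  expect_true(all(is.finite(rep$table1$F_omnibus)))
  # tidy/glance accessors
  expect_identical(tidy(rep), rep$table2)
  expect_identical(tidy(rep, "table1"), rep$table1)
  expect_equal(glance(rep)$n, 12)
  # degenerate cohort: every method equal to CHM
  tbl2 <- tbl
  for (nm in grep("^post_", names(tbl2), value = TRUE)) {
    tbl2[[nm]] <- tbl$post_CHM
  }
  rep2 <- build_report(tbl2)
  cmp2 <- rep2$table2[rep2$table2$method != "CHM", ]
  expect_true(all(cmp2$bias == 0))
  expect_true(all(is.na(cmp2$pearson_r)))
  expect_true(all(cmp2$degenerate))
  # missing column is named in the error
  expect_error(build_report(tbl[, setdiff(names(tbl), "post_TNP")]),
               class = "keratrace_missing_column", regexp = "post_TNP")
})
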