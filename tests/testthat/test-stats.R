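test_that("identical samples compare as indistinguishable", {
  x <- c(1, 2, 3, 4, 5)
  cmp <- wilcoxon_compare(x, x, rout_filter = FALSE)
  expect_gt(cmp$p_value, 0.9)
  expect_equal(cmp$table$median[1], cmp$table$median[2])
})

test_that("the canonical separated example gives the exact p of 0.1", {
  cmp <- wilcoxon_compare(c(1, 2, 3), c(10, 11, 12), rout_filter = FALSE)
  expect_equal(cmp$p_value, 0.1, tolerance = 1e-12)
  expect_match(cmp$method, "exact")
})

test_that("exact p-values match full enumeration for all small sizes", {
  set.seed(14)
  for (na in 3:6) {
    for (nb in 3:6) {
      a <- round(rnorm(na, 0, 3), 4)
      b <- round(rnorm(nb, 1, 3), 4)
      cmp <- wilcoxon_compare(a, b, rout_filter = FALSE)
      expect_equal(cmp$p_value, enum_ranksum_p(a, b), tolerance = 1e-10,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("the two-sided p is symmetric under group swap", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(wilcoxon_compare(a, b, rout_filter = FALSE)$p_value,
               wilcoxon_compare(b, a, rout_filter = FALSE)$p_value)
})

test_that("all-tied samples warn and report p = 1", {
  expect_warning(cmp <- wilcoxon_compare(rep(2, 5), rep(2, 4),
                                         rout_filter = FALSE), "tied")
  expect_equal(cmp$p_value, 1)
})

test_that("shifted lifetime distributions are detected with direction", {
  set.seed(6)
  long_group <- rnorm(100, 20, 3)   # like co-localized adhesions
  short_group <- rnorm(100, 15, 3)
  cmp <- wilcoxon_compare(long_group, short_group,
                          labels = c("pos", "neg"))
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$table$median[1], cmp$table$median[2])
})

test_that("order-statistic median CI has near-nominal coverage", {
  set.seed(77)
  hits <- vapply(1:500, function(i) {
    ci <- median_ci(rnorm(50), conf = 0.95)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("normality suite matches the independent omnibus reference", {
  set.seed(123)
  x <- round(rnorm(50, 10, 2), 6)
  res <- normality_suite(x)
  dago <- res[res$test == "D'Agostino-Pearson", ]
  # frozen reference values from an independent implementation
  expect_equal(dago$statistic, 0.45193486820239, tolerance = 1e-8)
  expect_equal(dago$p_value, 0.79774408049566, tolerance = 1e-8)
  heavy <- normality_suite(exp(x / 2))
  dago2 <- heavy[heavy$test == "D'Agostino-Pearson", ]
  expect_equal(dago2$statistic, 40.36087485315, tolerance = 1e-7)
  expect_equal(dago2$p_value, 1.7208673042e-09, tolerance = 1e-6)
  expect_true(all(heavy$p_value[heavy$test == "Shapiro-Wilk"] < 0.01))
})

test_that("normality suite calibrates on normal and rejects lognormal", {
  set.seed(11)
  normal_pass <- vapply(1:40, function(i) {
    all(normality_suite(rnorm(500))$p_value > 0.01)
  }, logical(1))
  expect_gt(mean(normal_pass), 0.7)
  lognormal_reject <- vapply(1:40, function(i) {
    res <- normality_suite(rlnorm(500))
    res$p_value[res$test == "Shapiro-Wilk"] < 0.01
  }, logical(1))
  expect_gte(mean(lognormal_reject), 0.95)
})

test_that("degenerate samples are marked unavailable, not fatal", {
  res <- normality_suite(rep(5, 20))
  expect_true(all(is.na(res$p_value)))
  expect_true(all(!is.na(res$note)))
  expect_error(normality_suite(1:5), "n >= 8")
})

test_that("linear regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4)
  exact <- suppressWarnings(linreg_correlate(x, 2 * x))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  set.seed(3)
  xs <- rnorm(60); ys <- 1.5 * xs + rnorm(60)
  r <- linreg_correlate(xs, ys)
  sxx <- sum((xs - mean(xs))^2)
  slope_oracle <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  expect_equal(r$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(r$intercept, mean(ys) - slope_oracle * mean(xs),
               tolerance = 1e-10)
  expect_error(linreg_correlate(rep(1, 10), rnorm(10)), "constant")
})

test_that("null regressions reject at roughly the nominal rate", {
  set.seed(21)
  rejections <- vapply(1:100, function(i) {
    linreg_correlate(rnorm(200), rnorm(200))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.12)
})

test_that("superplot tables aggregate replicates correctly", {
  sp1 <- superplot_table(c(1, 2, 3), rep("r1", 3), rep("g", 3))
  expect_equal(sp1$replicate_means$mean, mean(c(1, 2, 3)))

  sp2 <- superplot_table(c(1, 2, 3, 4), c("r1", "r1", "r2", "r2"),
                         rep("g", 4))
  expect_equal(sp2$replicate_means$mean, c(1.5, 3.5))
  # weighted mean of replicate means equals the pooled mean
  w <- sp2$replicate_means$n
  expect_equal(sum(w * sp2$replicate_means$mean) / sum(w), mean(1:4))

  set.seed(10)
  vals <- rnorm(60)
  reps <- sample(c("A", "B", "C"), 60, replace = TRUE)
  grps <- sample(c("g1", "g2"), 60, replace = TRUE)
  sp <- superplot_table(vals, reps, grps)
  oracle <- aggregate(vals, list(group = grps, replicate = reps), mean)
  oracle <- oracle[order(oracle$group, oracle$replicate), ]
  expect_equal(sp$replicate_means$mean, oracle$x)

  expect_error(superplot_table(1:3, c("a", NA, "b"), rep("g", 3)),
               "label")
})
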