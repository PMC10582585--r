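schemes <- builtin_bin_schemes()

test_that("threshold binning honors the printed edge inequalities", {
  expect_equal(assign_bins(25, schemes$char_freq), 1L)
  expect_equal(assign_bins(95, schemes$char_freq), 8L)
  expect_equal(assign_bins(30, schemes$char_freq), 1L)   # "<=30" boundary
  expect_equal(assign_bins(30.001, schemes$char_freq), 2L)
  expect_equal(assign_bins(0.8, schemes$ratio_q1q2_10), 1L)
  expect_equal(assign_bins(5.5, schemes$ratio_q1q2_10), 10L)
  expect_equal(assign_bins(c(20, 80.5), schemes$min_freq), c(1L, 8L))
  expect_equal(assign_bins(NA_real_, schemes$char_freq), NA_integer_)
})

test_that("every real value receives exactly one threshold bin", {
  grid <- seq(-5, 120, by = 0.01)
  for (sc in list(schemes$char_freq, schemes$bandwidth,
                  schemes$ratio_q1q2_10, schemes$ratio_q1q2_6)) {
    b <- assign_bins(grid, sc)
    expect_false(anyNA(b))
    expect_true(all(b >= 1L & b <= length(sc$edges) + 1L))
    expect_true(all(diff(b) >= 0))  # monotone in the value
  }
})

test_that("rank binning chunks sorted values into equal groups", {
  set.seed(5)
  v <- runif(40, 0.13, 0.37)
  b <- assign_bins(v, schemes$cwbw_rank5)
  expect_equal(sort(unique(b)), 1:8)
  expect_true(all(table(b) == 5))
  # group index respects the value ordering
  expect_true(all(tapply(v, b, max)[1:7] <= tapply(v, b, min)[2:8]))
  expect_error(assign_bins(runif(7), schemes$cwbw_rank5), "7.*5")
})

test_that("rank binning breaks ties by input order (stable)", {
  v <- c(2, 1, 1, 2)
  b <- assign_bins(v, bin_scheme("pairs", mode = "rank", group_size = 2L))
  expect_equal(b, c(2L, 1L, 1L, 2L))
})

test_that("correlate_group_means reproduces closed-form cases", {
  # two groups with distinct means -> |r| = 1
  res2 <- correlate_group_means(c(1, 2, 5, 6), c(10, 12, 3, 4),
                                labels = c(1, 1, 2, 2))
  expect_equal(abs(res2$r), 1)

  # group means constructed on an exact line -> r = -1
  x <- c(1, 1, 2, 2, 3, 3)
  y <- 3 - 2 * x
  res <- correlate_group_means(x, y, labels = rep(1:3, each = 2))
  expect_equal(res$r, -1)
  expect_equal(res$n_groups, 3L)
})

test_that("correlate_group_means matches a brute-force Pearson oracle", {
  set.seed(31)
  x <- rnorm(120); y <- 0.6 * x + rnorm(120, 0, 0.5)
  labels <- sample(1:8, 120, replace = TRUE)
  res <- correlate_group_means(x, y, labels)
  mx <- tapply(x, labels, mean); my <- tapply(y, labels, mean)
  expect_equal(res$r, pearson_manual(as.numeric(mx), as.numeric(my)),
               tolerance = 1e-12)
  # p from the two-sided t distribution with n_groups - 2 df
  tt <- res$r * sqrt((res$n_groups - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(abs(tt), res$n_groups - 2,
                                   lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("correlation is invariant to bin relabeling and post-hoc affine maps", {
  set.seed(32)
  x <- rnorm(60); y <- x + rnorm(60)
  labels <- sample(1:6, 60, replace = TRUE)
  base <- correlate_group_means(x, y, labels)
  perm <- c(3, 1, 6, 2, 5, 4)[labels]
  expect_equal(correlate_group_means(x, y, perm)$r, base$r,
               tolerance = 1e-12)
  # positive affine transform of one axis leaves Pearson r unchanged
  expect_equal(correlate_group_means(2.5 * x + 7, y, labels)$r, base$r,
               tolerance = 1e-12)
})

test_that("transforms apply per value before group means; errors are typed", {
  x <- c(10, 1000, 100, 10000)
  y <- c(1, 3, 2, 4)
  res <- correlate_group_means(x, y, labels = c(1, 1, 2, 2),
                               transform_x = "log10")
  # mean of logs, not log of means: (1+3)/2 and (2+4)/2
  expect_equal(res$summaries$mean_x, c(2, 3))
  expect_error(correlate_group_means(c(-1, 2, 3, 4), y, c(1, 1, 2, 2),
                                     transform_x = "log10"), "positive")
  expect_error(correlate_group_means(x, y, labels = rep(1, 4)),
               "at least 2")
  expect_error(correlate_group_means(c(1, 1, 1, 1), y, c(1, 1, 2, 2)),
               "degenerate_means")
})

test_that("one-way ANOVA matches the independent decomposition and lm", {
  set.seed(41)
  values <- c(rnorm(8, 0), rnorm(12, 0.5), rnorm(7, 2))
  labels <- rep(c("a", "b", "c"), c(8, 12, 7))
  cmp <- compare_groups(values, labels)
  expect_equal(cmp$f_stat, anova_f_manual(values, labels),
               tolerance = 1e-10)
  ref <- anova(lm(values ~ factor(labels)))
  expect_equal(cmp$f_stat, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(cmp$df_between, 2L)
  expect_equal(cmp$df_within, 24L)
})

test_that("two-group F equals the squared pooled-variance t statistic", {
  set.seed(42)
  a <- rnorm(10); b <- rnorm(12, 1)
  cmp <- compare_groups(c(a, b), rep(c("a", "b"), c(10, 12)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("SNK separates an extreme group and only that group", {
  set.seed(43)
  values <- c(rnorm(6, 0, 0.01), rnorm(6, 0, 0.01), rnorm(6, 10, 0.01))
  labels <- rep(c("a", "b", "c"), each = 6)
  cmp <- compare_groups(values, labels)
  expect_lt(cmp$p_value, 1e-6)
  ph <- cmp$posthoc
  sig_pairs <- ph[ph$significant %in% TRUE, c("group1", "group2")]
  pairs <- paste(sig_pairs$group1, sig_pairs$group2)
  expect_setequal(pairs, c("a c", "b c"))
})

test_that("post hoc is gated on the omnibus test", {
  set.seed(44)
  values <- rnorm(30)
  labels <- rep(c("a", "b", "c"), each = 10)
  cmp <- compare_groups(values, labels, alpha = 1e-6)
  expect_null(cmp$posthoc)
  expect_error(compare_groups(rep(1, 10), rep(c("a", "b"), 5)),
               "degenerate_groups")
  expect_error(compare_groups(1:3, c("a", "b", "c")), "at least 2")
})

test_that("dataset consolidation keeps maxima for maxima, minima for minima", {
  v <- c(10, 30, 20, 5)
  sp <- c("a", "a", "b", "b")
  expect_equal(unname(consolidate_phenotype(v, sp, "max")), c(30, 20))
  expect_equal(unname(consolidate_phenotype(v, sp, "min")), c(10, 5))
})
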