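test_that("percent accuracy matches the worked examples and is antisymmetric", {
  expect_equal(accuracy_pct(262, 250), 4.8)
  expect_equal(round(accuracy_pct(262, 250)), 5)
  expect_equal(accuracy_pct(233, 250), -6.8)
  expect_equal(round(accuracy_pct(233, 250)), -7)
  expect_equal(accuracy_pct(100, 100), 0)
  for (d in c(1, 7, 23)) {
    expect_equal(accuracy_pct(100 + d, 100), -accuracy_pct(100 - d, 100))
  }
})

test_that("run summaries report mean error, range proportions and mode ties", {
  s <- summarize_runs(c(98, 99, 100, 101, 102), target = 100)
  expect_equal(s$prop_98_102, 1.0)
  expect_equal(s$mean_pct_error, 0)
  expect_equal(sort(s$mode), c(98, 99, 100, 101, 102))  # all tied
  s2 <- summarize_runs(rep(100, 8), target = 100)
  expect_equal(s2$ci95_halfwidth, 0)
  expect_equal(s2$mode, 100L)
  expect_true(s2$prop_98_102 <= s2$prop_95_105)
  # single run: interval statistics unavailable, not fabricated
  s1 <- summarize_runs(97, target = 100)
  expect_true(is.na(s1$ci95_halfwidth))
  expect_true(is.na(s1$shapiro_p))
})

test_that("normality and skew on integer-rounded draws match the reference test", {
  set.seed(101)
  x <- round(rnorm(500, 100, 4))
  s <- summarize_runs(x, target = 100)
  expect_equal(s$shapiro_p, shapiro.test(x)$p.value, tolerance = 1e-6)
  set.seed(7)
  left <- round(100 - rexp(300, 0.2))
  expect_equal(summarize_runs(left, target = 100)$skew_direction, "left")
})

test_that("summary-statistic ANOVA reproduces the raw-data ANOVA", {
  set.seed(55)
  k <- 5
  raw <- data.frame(label = rep(letters[1:k], times = c(8, 12, 10, 15, 9)))
  raw$value <- 100 + c(0, 3, -2, 8, 1)[as.integer(factor(raw$label))] +
    rnorm(nrow(raw), 0, 4)
  a_raw <- zscore_anova(raw)
  summ <- do.call(rbind, lapply(split(raw$value, raw$label), function(v) {
    data.frame(n = length(v), mean = mean(v),
               ci = qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v)))
  }))
  summ$label <- rownames(summ)
  a_sum <- zscore_anova(summ, ci_quantile = "t")
  expect_equal(a_sum$table$SS, a_raw$table$SS, tolerance = 1e-10)
  expect_equal(a_sum$table$F[1], a_raw$table$F[1], tolerance = 1e-10)
  expect_equal(a_sum$groups$letters, a_raw$groups$letters)
})

test_that("raw-route Tukey pairwise p-values match the reference implementation", {
  set.seed(66)
  raw <- data.frame(label = rep(c("lo", "mid", "hi"), each = 10),
                    value = rnorm(30, rep(c(10, 12, 20), each = 10), 3))
  a <- zscore_anova(raw, bonferroni = FALSE)
  fit <- aov(value ~ label, data = raw)
  ref <- TukeyHSD(fit)$label
  key <- paste(a$pairwise$group1, a$pairwise$group2)
  for (j in seq_len(nrow(ref))) {
    parts <- strsplit(rownames(ref)[j], "-")[[1]]
    idx <- which(key == paste(parts[2], parts[1]) | key == paste(parts[1], parts[2]))
    expect_equal(a$pairwise$p[idx], unname(ref[j, "p adj"]), tolerance = 1e-8)
  }
})

test_that("equal group means give zero between-group sum of squares", {
  g <- data.frame(label = c("a", "b", "c"), n = c(5, 7, 6),
                  mean = c(10, 10, 10), ci = c(1, 1.2, 0.9))
  a <- zscore_anova(g)
  expect_equal(a$table$SS[1], 0)
  expect_equal(a$table$F[1], 0)
  expect_true(all(a$groups$letters == "a"))
})

test_that("published-table recovery yields the printed degrees of freedom and SS", {
  t1 <- data.frame(label = c("2.5", "3", "3.5", "4", "4.5", "5", "6", "7", "8"),
                   n = c(10, 21, 20, 20, 21, 13, 8, 6, 5),
                   mean = c(99.7, 97.2, 97.5, 96.2, 97.5, 95.9, 102.9, 135.5, 132.6),
                   ci = c(1.60, 1.22, 1.74, 2.21, 1.66, 8.77, 4.16, 33.84, 34.00))
  a <- zscore_anova(t1, ci_quantile = "normal")
  expect_equal(a$table$df[1], 8)
  expect_equal(a$table$df[2], 115)
  expect_equal(a$table$SS[1], 13791.628, tolerance = 1e-3)
  expect_equal(a$table$SS[2], 19641.1457, tolerance = 2e-3)
  # under plain HSD the printed letter pattern is recovered exactly:
  # thresholds up to 6 share one letter, 7 and 8 share another
  h <- zscore_anova(t1, ci_quantile = "normal", bonferroni = FALSE)
  expect_true(length(unique(h$groups$letters[1:7])) == 1)
  expect_true(length(unique(h$groups$letters[8:9])) == 1)
  expect_false(h$groups$letters[1] == h$groups$letters[8])
  # Bonferroni tightening never declares the 7/8 groups equal to the low ones
  pw <- a$pairwise
  high_vs_low <- (pw$group1 %in% c("7", "8")) != (pw$group2 %in% c("7", "8"))
  low_only <- !(pw$group1 %in% c("6", "7", "8")) & !(pw$group2 %in% c("6", "7", "8"))
  expect_true(all(pw$significant[high_vs_low & pw$group1 != "6" & pw$group2 != "6"]))
  expect_false(any(pw$significant[low_only]))
})

test_that("rate-accuracy correlation handles collinear and degenerate inputs", {
  d <- data.frame(mean_lps = 1:6, pct_error = 2 * (1:6) + 3)
  expect_equal(lps_accuracy_correlation(d)$r, 1)
  d2 <- data.frame(mean_lps = 1:6, pct_error = -(1:6))
  expect_equal(lps_accuracy_correlation(d2)$r, -1)
  d3 <- data.frame(mean_lps = rep(5, 6), pct_error = rnorm(6))
  expect_true(is.na(lps_accuracy_correlation(d3)$r))
})

test_that("summary t-test agrees with the reference on raw data", {
  expect_equal(two_sample_ttest(10, 2, 5, 10, 2, 5),
               list(t = 0, df = 8, p = 1))
  set.seed(3)
  x <- rnorm(12, 10, 2); y <- rnorm(9, 12, 2.5)
  ours <- two_sample_ttest(mean(x), sd(x), 12, mean(y), sd(y), 9)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  ours_w <- two_sample_ttest(mean(x), sd(x), 12, mean(y), sd(y), 9, welch = TRUE)
  ref_w <- t.test(x, y)
  expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-10)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)
})

test_that("flow-rate comparison from rounded summaries is overwhelmingly significant", {
  tt <- two_sample_ttest(0.77, 0.012, 6, 0.48, 0.007, 7)
  expect_equal(tt$df, 11)
  expect_lt(tt$p, 1e-12)  # raw-data analysis reported ~1e-16
})

test_that("z tail probability behaves as a two-sided Gaussian exceedance", {
  expect_equal(signif(z_error_probability(3.5), 2), 0.00047)
  expect_equal(z_error_probability(0), 1)
  expect_equal(z_error_probability(qnorm(0.975)), 0.05)
  z <- seq(0, 6, by = 0.25)
  expect_true(all(diff(z_error_probability(z)) < 0))
})

test_that("disagreement rate is a simple percentage", {
  expect_equal(round(disagreement_rate(275, 477), 1), 57.7)
  expect_equal(disagreement_rate(275, 477), 100 * 275 / 477)
  expect_equal(disagreement_rate(0, 10), 0)
  expect_equal(round(disagreement_rate(1, 3), 1), 33.3)
  expect_error(disagreement_rate(5, 3), "in \\[0, n_total\\]")
})
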