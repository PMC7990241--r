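test_that("rank-sum p matches the exhaustive enumeration oracle on the textbook case", {
  res <- wilcoxon_test(c(1, 2, 3, 4, 5, 6),
                       c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$p_value, 0.1)  # 2 of the 20 assignments are as extreme
  expect_equal(res$p_value, rank_sum_enum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("identical groups give the maximal rank-sum p", {
  res <- wilcoxon_test(rep(c(5, 7, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 1)
})

test_that("exact-path p equals exhaustive enumeration across small group sizes", {
  for (nx in c(2, 3, 5)) {
    for (ny in c(3, 4, 6)) {
      vals <- withr::with_seed(nx * 100 + ny, rnorm(nx + ny))
      groups <- rep(c("a", "b"), c(nx, ny))
      got <- wilcoxon_test(vals, groups)$p_value
      want <- rank_sum_enum_p(vals[seq_len(nx)], vals[-seq_len(nx)])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("groups of fewer than 2 samples are rejected", {
  expect_error(wilcoxon_test(1:4, c("a", "b", "b", "b")), "at least 2")
  expect_error(wilcoxon_test(1:4, c("a", "a", "a", "a")), "exactly 2")
})

test_that("two-group Tukey p equals the pooled-variance t-test p", {
  for (s in 1:25) {
    vals <- withr::with_seed(s, rnorm(11))
    groups <- rep(c("a", "b"), c(5, 6))
    res <- anova_tukey(vals, groups)
    want <- pooled_t_p(vals[1:5], vals[6:11])
    expect_equal(res$tukey$p_value, want, tolerance = 1e-8)
    expect_equal(res$p_value, want, tolerance = 1e-8)  # F-test == t-test, k = 2
  }
})

test_that("Tukey pairwise p agrees with stats::TukeyHSD", {
  vals <- withr::with_seed(7, rnorm(18))
  groups <- rep(c("g1", "g2", "g3"), each = 6)
  res <- anova_tukey(vals, groups)
  fit <- stats::aov(vals ~ factor(groups))
  ref <- stats::TukeyHSD(fit)[[1]]
  ref_keys <- rownames(ref)
  for (i in seq_len(nrow(res$tukey))) {
    key1 <- paste0(res$tukey$group2[i], "-", res$tukey$group1[i])
    key2 <- paste0(res$tukey$group1[i], "-", res$tukey$group2[i])
    p_ref <- ref[match(TRUE, ref_keys %in% c(key1, key2)), "p adj"]
    expect_equal(res$tukey$p_value[i], unname(p_ref), tolerance = 1e-8)
  }
})

test_that("identical group distributions give F = 0 and unit p-values", {
  vals <- rep(c(1, 2, 3), 3)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(vals, groups)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$tukey$p_value, rep(1, 3))
})

test_that("anova is invariant to sample order and flags zero pooled variance", {
  vals <- withr::with_seed(3, rnorm(12))
  groups <- rep(c("a", "b", "c"), each = 4)
  perm <- withr::with_seed(4, sample.int(12))
  r1 <- anova_tukey(vals, groups)
  r2 <- anova_tukey(vals[perm], groups[perm])
  expect_equal(r1$f_statistic, r2$f_statistic)
  expect_equal(dplyr::arrange(r1$tukey, group1, group2),
               dplyr::arrange(r2$tukey, group1, group2))
  degen <- anova_tukey(rep(c(1, 5), each = 3), rep(c("a", "b"), each = 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
})

test_that("Tukey HSD is conservative relative to the pooled-variance pairwise t for k > 2", {
  for (s in 1:10) {
    vals <- withr::with_seed(100 + s, rnorm(15))
    groups <- rep(c("a", "b", "c"), each = 5)
    res <- anova_tukey(vals, groups)
    # oracle: pairwise t using the same pooled within-group MSE and error df
    fit <- stats::aov(vals ~ factor(groups))
    sm <- summary(fit)[[1]]
    mse <- sm[["Mean Sq"]][2]
    df_err <- sm[["Df"]][2]
    for (i in seq_len(nrow(res$tukey))) {
      x <- vals[groups == res$tukey$group1[i]]
      y <- vals[groups == res$tukey$group2[i]]
      t_stat <- (mean(x) - mean(y)) / sqrt(mse * (1 / 5 + 1 / 5))
      p_t <- 2 * stats::pt(abs(t_stat), df_err, lower.tail = FALSE)
      expect_gte(res$tukey$p_value[i], p_t - 1e-12)
    }
  }
})

test_that("log2 fold changes are antisymmetric and flag non-positive means", {
  data <- tibble::tibble(up = c(4, 4, 1, 1), flat = c(2, 2, 2, 2),
                         neg = c(-1, -1, 1, 1))
  groups <- rep(c("A", "B"), each = 2)
  fc <- fold_changes(data, groups, c("A", "B"))
  expect_equal(fc$log2_fc[1], 2)
  expect_equal(fc$log2_fc[2], 0)
  expect_false(fc$fc_defined[3])
  rev_fc <- fold_changes(data, groups, c("B", "A"))
  expect_equal(rev_fc$log2_fc[1:2], -fc$log2_fc[1:2])
})

test_that("volcano selection applies both thresholds jointly", {
  tab <- tibble::tibble(
    metabolite = c("a", "b", "c", "d"),
    log2_fc = c(1.5, 0.5, -2, NA),
    p_value = c(0.01, 0.001, 0.2, 0.001)
  )
  sel <- volcano_select(tab)
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE, FALSE))
  all_in <- volcano_select(tab, min_abs_log2_fc = 0, max_p = 1)
  expect_equal(all_in$selected, c(TRUE, TRUE, TRUE, FALSE))  # NA never selected
})

test_that("metabolite_stats uses Wilcoxon for 2 groups and Tukey pair p for 3", {
  cm <- correlated_matrix(12, 4, seed = 5)
  data <- cm$data
  g2 <- rep(c("x", "y"), each = 6)
  res2 <- metabolite_stats(data, g2)
  expect_equal(res2$p_value, wilcoxon_tests(data, g2)$p_value)
  expect_true(all(c("log2_fc", "p_adjusted", "selected") %in% names(res2)))
  expect_equal(res2$p_adjusted, p.adjust(res2$p_value, "BH"))

  g3 <- rep(c("x", "y", "z"), each = 4)
  res3 <- metabolite_stats(data, g3, pair = c("x", "z"))
  ref <- anova_tukey_tests(data, g3)
  want <- vapply(ref$tukey, function(tk) {
    tk$p_value[(tk$group1 == "x" & tk$group2 == "z") |
                 (tk$group1 == "z" & tk$group2 == "x")][1]
  }, numeric(1))
  expect_equal(res3$p_value, want)
  expect_true("anova_p" %in% names(res3))
})

test_that("null simulations keep the Wilcoxon type-I error near nominal", {
  sim <- simulate_dataset(simulation_config(
    n_samples_per_group = 10, n_metabolites = 400, n_differential = 0,
    seed = 1301))
  res <- wilcoxon_tests(sim$truth$clean, sim$table$group)
  rate <- mean(res$p_value <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("power grows with sample size under a fixed group shift", {
  med_p <- vapply(c(5, 10, 20), function(n) {
    sim <- withr::with_seed(1400 + n, {
      g <- rep(c("a", "b"), each = n)
      m <- matrix(rnorm(2 * n * 60), 2 * n, 60)
      m[g == "b", ] <- m[g == "b", ] + 2  # 2-sd shift
      colnames(m) <- paste0("m", 1:60)
      list(data = tibble::as_tibble(as.data.frame(m)), groups = g)
    })
    stats::median(wilcoxon_tests(sim$data, sim$groups)$p_value)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
})
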