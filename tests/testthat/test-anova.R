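balanced_table <- function(y, a, b, n) {
  tibble::tibble(
    group = rep(rep(paste0("g", seq_len(a)), each = b * n)),
    window = rep(rep(paste0("w", seq_len(b)), each = n), times = a),
    channel = "cbf_pu",
    pct_change = y
  )
}

test_that("equal cell means give zero factor sums of squares", {
  # every cell is {4, 6}: all cell means 5, within-cell variance 2
  tab <- balanced_table(rep(c(4, 6), times = 6), a = 2, b = 3, n = 2)
  fit <- two_way_anova(tab)
  td <- tidy(fit)
  expect_equal(td$ss[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(td$statistic[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(td$ss[4], 12)   # 12 squared deviations of 1
  expect_equal(glance(fit)$df.residual, 6)
})

test_that("the decomposition matches the nested least-squares oracle", {
  set.seed(42)
  y <- rnorm(12, mean = rep(c(0, 1, 2, 0), each = 3))
  tab <- balanced_table(y, a = 2, b = 2, n = 3)
  fit <- tidy(two_way_anova(tab))
  oracle <- anova_oracle(y, tab$group, tab$window)
  expect_equal(fit$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(fit$df, oracle$df)
  expect_equal(fit$statistic[1:3], oracle$f, tolerance = 1e-8)
  expect_equal(fit$p.value[1:3], oracle$p, tolerance = 1e-8)
})

test_that("random balanced tables agree with the oracle over many draws", {
  set.seed(7)
  for (i in 1:100) {
    a <- sample(2:3, 1)
    b <- sample(2:5, 1)
    n <- sample(2:5, 1)
    y <- rnorm(a * b * n, mean = rnorm(a * b, sd = 2)[rep(seq_len(a * b), each = n)])
    tab <- balanced_table(y, a, b, n)
    fit <- tidy(two_way_anova(tab))
    oracle <- anova_oracle(y, tab$group, tab$window)
    expect_equal(fit$ss, oracle$ss, tolerance = 1e-8)
    expect_equal(fit$statistic[1:3], oracle$f, tolerance = 1e-8)
    expect_equal(fit$p.value[1:3], oracle$p, tolerance = 1e-8)
  }
})

test_that("adding a constant leaves the decomposition unchanged", {
  set.seed(3)
  y <- rnorm(24)
  tab <- balanced_table(y, a = 2, b = 3, n = 4)
  tab2 <- dplyr::mutate(tab, pct_change = pct_change + 123.4)
  expect_equal(tidy(two_way_anova(tab))[c("ss", "statistic")],
               tidy(two_way_anova(tab2))[c("ss", "statistic")],
               tolerance = 1e-8)
})

test_that("degenerate designs are rejected with guidance", {
  tab <- balanced_table(rnorm(12), a = 2, b = 3, n = 2)
  expect_error(two_way_anova(tab[-1, ]), "Unbalanced")
  expect_error(two_way_anova(balanced_table(rnorm(6), a = 2, b = 3, n = 1)),
               "one observation per cell")
  one_group <- dplyr::mutate(tab, group = "g1")
  expect_error(two_way_anova(one_group), ">= 2 levels")
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5)
  expect_equal(sidak_adjust(0.5, 10), 1 - 0.5^10)
  expect_equal(sidak_adjust(0.9, 50), 1)
  grid <- expand.grid(p = c(0, 0.001, 0.01, 0.1, 0.5, 0.9, 1), m = 1:8)
  adj <- sidak_adjust(grid$p, 1)  # m applied per column below
  for (m in 1:8) {
    a <- sidak_adjust(grid$p, m)
    expect_equal(a, pmin(1, 1 - (1 - grid$p)^m))
    expect_true(all(a >= grid$p))
    expect_true(all(diff(sidak_adjust(sort(grid$p), m)) >= 0))
    if (m > 1) expect_true(all(a >= sidak_adjust(grid$p, m - 1)))
  }
  expect_error(sidak_adjust(0.05, 0), "m")
  expect_error(sidak_adjust(1.5, 2), "raw_p")
})

test_that("pairwise comparisons use the pooled residual variance", {
  set.seed(11)
  # identical group data in every window: all raw p exactly 1
  y_half <- rnorm(12)
  tab <- balanced_table(c(y_half, y_half), a = 2, b = 3, n = 4)
  # reorder so both groups see the same values per window
  tab$pct_change <- rep(rnorm(3 * 4), times = 2)
  pw <- pairwise_group_comparisons(tab)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_raw, rep(1, 3))
  expect_equal(pw$p_sidak, rep(1, 3))
  expect_false(any(pw$significant))

  set.seed(12)
  tab2 <- balanced_table(rnorm(24, rep(c(0, 3), each = 12)), a = 2, b = 3, n = 4)
  pw2 <- pairwise_group_comparisons(tab2)
  expect_true(all(pw2$p_sidak >= pw2$p_raw))
  expect_true(all(pw2$p_sidak <= 1))
})

test_that("the programmed group effect is detected in most simulated cohorts", {
  # sham vs sGVS cohorts at the documented effect sizes, n = 8 per group:
  # the stimulation-window CBF contrast should be significant nearly always
  hits <- vapply(1:15, function(r) {
    recs <- simulate_cohort(
      cohort_spec(n_per_group = 8, groups = c("sham", "sgvs"),
                  sample_rate = 2, master_seed = 5000L + r),
      params = list(sgvs = do.call(response_params, utils::modifyList(
        unclass(preset_params("sgvs")), list(responder_prob = 1)))))
    long <- build_long_table(
      purrr::map_dfr(recs, ~ percent_change(summarize_sections(.x))))
    pw <- pairwise_group_comparisons(
      dplyr::filter(long, channel == "cbf_pu"))
    pw$significant[pw$window == "Stimulation"]
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
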