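three_groups <- function(a, b, c_) {
  tibble::tibble(group = rep(c("WT", "AD", "ADT"), times = c(length(a), length(b), length(c_))),
                 value = c(a, b, c_))
}

test_that("identical groups give null statistics across all tests", {
  df <- three_groups(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  lev <- levene_test(df, value, group)
  expect_equal(lev$statistic, 0)
  expect_equal(lev$p_value, 1)
  av <- anova_scheffe(df, value, group)
  expect_equal(av$statistic, 0)
  expect_equal(av$p_value, 1)
  kw_const <- kruskal_bonferroni(three_groups(c(2, 2), c(2, 2), c(2, 2)),
                                 value, group)
  expect_equal(kw_const$statistic, 0)
  expect_equal(kw_const$p_value, 1)
})

test_that("ANOVA F matches hand-computed sums of squares to 1e-10", {
  a <- c(6.1, 5.8, 7.2, 6.6, 5.9)
  b <- c(4.9, 5.2, 4.4, 5.8, 5.1)
  c_ <- c(7.4, 8.1, 6.9, 7.7, 8.0)
  df <- three_groups(a, b, c_)
  av <- anova_scheffe(df, value, group)

  # independent hand computation
  all_v <- c(a, b, c_)
  grand <- mean(all_v)
  ssb <- 5 * ((mean(a) - grand)^2 + (mean(b) - grand)^2 + (mean(c_) - grand)^2)
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2) + sum((c_ - mean(c_))^2)
  f_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(av$statistic, f_hand, tolerance = 1e-10)
  expect_equal(av$df, c(2, 12))

  # cross-check against the standard linear-model fit
  fit <- summary(stats::aov(value ~ group, data = df))[[1]]
  expect_equal(av$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(av$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)

  # Scheffe pairwise p for one pair, from its definition
  mse <- ssw / 12
  s2 <- (mean(a) - mean(b))^2 / (mse * (1 / 5 + 1 / 5))
  p_ab <- stats::pf(s2 / 2, 2, 12, lower.tail = FALSE)
  pw <- av$pairwise
  got <- pw$p_adjusted[(pw$group1 == "WT" & pw$group2 == "AD") |
                       (pw$group1 == "AD" & pw$group2 == "WT")]
  expect_equal(got, p_ab, tolerance = 1e-10)
})

test_that("Scheffe is never less conservative than an unadjusted t test", {
  withr::local_seed(71)
  for (i in 1:20) {
    df <- three_groups(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
    av <- anova_scheffe(df, value, group)
    # pooled-variance pairwise t (same MSE as the ANOVA), unadjusted
    pt <- stats::pairwise.t.test(df$value, df$group,
                                 p.adjust.method = "none", pool.sd = TRUE)
    for (r in seq_len(nrow(av$pairwise))) {
      g1 <- av$pairwise$group1[r]; g2 <- av$pairwise$group2[r]
      p_t <- pt$p.value[g2, g1]
      if (is.na(p_t)) p_t <- pt$p.value[g1, g2]
      expect_gte(av$pairwise$p_adjusted[r], p_t - 1e-12)
    }
  }
})

test_that("Kruskal-Wallis pairwise adjustment is Bonferroni by definition", {
  withr::local_seed(72)
  df <- three_groups(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  kw <- kruskal_bonferroni(df, value, group)
  expect_equal(kw$pairwise$p_adjusted,
               pmin(1, 3 * kw$pairwise$p_raw))
  ref <- stats::kruskal.test(value ~ group, data = df)
  expect_equal(kw$statistic, unname(ref$statistic))
  expect_equal(kw$p_value, ref$p.value)
})

test_that("Levene detects a ninefold variance ratio and holds its size", {
  power_hits <- withr::with_seed(73, vapply(1:100, function(i) {
    df <- tibble::tibble(group = rep(c("a", "b"), each = 200),
                         value = c(rnorm(200, 0, 1), rnorm(200, 0, 3)))
    levene_test(df, value, group)$p_value < 0.01
  }, logical(1)))
  expect_gte(mean(power_hits), 0.95)

  null_rej <- withr::with_seed(74, vapply(1:1000, function(i) {
    df <- three_groups(rnorm(20), rnorm(20), rnorm(20))
    levene_test(df, value, group)$p_value < 0.05
  }, logical(1)))
  expect_gte(mean(null_rej), 0.03)
  expect_lte(mean(null_rej), 0.07)
})

test_that("Kruskal-Wallis has power against a 1 SD median shift", {
  rej <- withr::with_seed(75, vapply(1:200, function(i) {
    df <- three_groups(rnorm(30), rnorm(30), rnorm(30, 1))
    kruskal_bonferroni(df, value, group)$p_value < 0.05
  }, logical(1)))
  expect_gt(mean(rej), 0.8)
})

test_that("statistics are invariant to row permutation", {
  withr::local_seed(76)
  df <- three_groups(rnorm(9), rnorm(9, 0.4), rnorm(9, 0.8))
  shuf <- df[sample(nrow(df)), ]
  expect_equal(anova_scheffe(shuf, value, group)$statistic,
               anova_scheffe(df, value, group)$statistic)
  expect_equal(kruskal_bonferroni(shuf, value, group)$statistic,
               kruskal_bonferroni(df, value, group)$statistic)
  expect_equal(levene_test(shuf, value, group)$statistic,
               levene_test(df, value, group)$statistic)
})

test_that("group tables are validated", {
  expect_error(levene_test(tibble::tibble(group = "a", value = 1),
                           value, group),
               class = "ripplepac_validation_error")
  expect_error(anova_scheffe(three_groups(1, c(1, 2), c(1, 2)), value, group),
               class = "ripplepac_validation_error")
  expect_error(levene_test(three_groups(c(1, NA), c(1, 2), c(1, 2)),
                           value, group),
               class = "ripplepac_validation_error")
})

test_that("group_report routes by variance and normality checks", {
  withr::local_seed(78)
  normal <- three_groups(rnorm(15), rnorm(15, 0.5), rnorm(15, 1))
  rep_n <- group_report(normal, value, group)
  expect_equal(rep_n$route, "anova")

  skewed <- three_groups(rlnorm(15, 0, 1.5), rlnorm(15, 1, 0.2),
                         rlnorm(15, 2, 2))
  rep_s <- group_report(skewed, value, group)
  expect_equal(rep_s$route, "kruskal")

  forced <- group_report(skewed, value, group, route = "anova")
  expect_equal(forced$route, "anova")

  # multi-metric long table gives one row per metric
  long <- dplyr::bind_rows(
    dplyr::mutate(normal, metric = "m1"),
    dplyr::mutate(skewed, metric = "m2"))
  rep_m <- group_report(long, value, group, metric)
  expect_equal(sort(rep_m$metric), c("m1", "m2"))
  expect_equal(nrow(rep_m$summary[[1]]), 3)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_m, path)
  back <- jsonlite::read_json(path)
  expect_equal(names(back), c("m1", "m2"))
})
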