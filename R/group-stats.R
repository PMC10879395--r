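#' Levene's test for homogeneity of variances
#'
#' Mean-centered Levene test (the classic variant): a one-way ANOVA on
#' the absolute deviations of each value from its group mean.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the metric values and
#'   group labels.
#' @return A `test_report`: list with `test`, `statistic`, `df`
#'   (numerator, denominator), `p_value`, `pairwise` (empty tibble).
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5), y = rnorm(10))
#' levene_test(df, y, g)
#' @export
levene_test <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  check_group_table(y, g)
  # near-perfect fits (tiny equal groups) warn inside the F test; the
  # non-finite-statistic fallback below covers that case
  lt <- suppressWarnings(car::leveneTest(y ~ g, center = mean))
  stat <- lt$`F value`[1]
  p <- lt$`Pr(>F)`[1]
  if (!is.finite(stat)) { stat <- 0; p <- 1 }
  new_test_report("levene", stat, c(lt$Df[1], lt$Df[2]), p)
}

#' One-way ANOVA with Scheffe post-hoc comparisons
#'
#' Omnibus F test across groups followed by Scheffe's method for all
#' pairwise contrasts: for groups `i, j` the statistic
#' `S^2 = (m_i - m_j)^2 / (MSE * (1/n_i + 1/n_j))` is referred to
#' `(k - 1) * F(k-1, N-k)`, making the family-wise error controlled over
#' every possible contrast (hence never less conservative than an
#' unadjusted pairwise t test).
#'
#' @inheritParams levene_test
#' @return A `test_report` with the omnibus F, df `(k-1, N-k)`, p value,
#'   and a `pairwise` tibble (`group1`, `group2`, `diff`, `statistic`,
#'   `p_adjusted`, `method = "scheffe"`). All-identical values give a
#'   degenerate report with `F = 0`, `p = 1`.
#' @export
anova_scheffe <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  check_group_table(y, g)
  k <- nlevels(g)
  n <- length(y)
  ni <- tabulate(g)
  mi <- tapply(y, g, mean)
  grand <- mean(y)
  ss_between <- sum(ni * (mi - grand)^2)
  ss_within <- sum((y - mi[as.integer(g)])^2)
  df1 <- k - 1
  df2 <- n - k
  mse <- ss_within / df2

  if (mse == 0 && ss_between == 0) {
    pw <- scheffe_pairs(levels(g), mi, ni, mse = NA_real_, df1, df2,
                        degenerate = TRUE)
    return(new_test_report("anova", 0, c(df1, df2), 1, pairwise = pw))
  }
  f <- (ss_between / df1) / mse
  p <- pf(f, df1, df2, lower.tail = FALSE)
  pw <- scheffe_pairs(levels(g), mi, ni, mse, df1, df2)
  new_test_report("anova", f, c(df1, df2), p, pairwise = pw)
}

scheffe_pairs <- function(lev, mi, ni, mse, df1, df2, degenerate = FALSE) {
  pairs <- utils::combn(seq_along(lev), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    if (degenerate || mse == 0) {
      stat <- 0; p <- 1
    } else {
      s2 <- (mi[i] - mi[j])^2 / (mse * (1 / ni[i] + 1 / ni[j]))
      stat <- s2 / df1
      p <- pf(stat, df1, df2, lower.tail = FALSE)
    }
    tibble(group1 = lev[i], group2 = lev[j],
           diff = unname(mi[i] - mi[j]), statistic = unname(stat),
           p_adjusted = unname(p), method = "scheffe")
  })
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected) across groups; pairwise
#' Wilcoxon rank-sum tests (normal approximation with continuity
#' correction) with Bonferroni adjustment `p_adj = min(1, m * p)` over
#' the `m = k(k-1)/2` pairs.
#'
#' @inheritParams levene_test
#' @return A `test_report` with H, df `k-1`, p value and the pairwise
#'   tibble (`p_raw`, `p_adjusted`, `method = "bonferroni"`).
#' @export
kruskal_bonferroni <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  check_group_table(y, g)
  lev <- levels(g)
  m <- length(lev) * (length(lev) - 1) / 2
  if (max(y) == min(y)) {
    pairs <- utils::combn(lev, 2)
    pw <- tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                 statistic = 0, p_raw = 1, p_adjusted = 1,
                 method = "bonferroni")
    return(new_test_report("kruskal", 0, c(length(lev) - 1, NA), 1,
                           pairwise = pw))
  }
  kt <- kruskal.test(y ~ g)
  pairs <- utils::combn(lev, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(c_) {
    yi <- y[g == pairs[1, c_]]
    yj <- y[g == pairs[2, c_]]
    wt <- suppressWarnings(wilcox.test(yi, yj, exact = FALSE, correct = TRUE))
    tibble(group1 = pairs[1, c_], group2 = pairs[2, c_],
           statistic = unname(wt$statistic), p_raw = wt$p.value,
           p_adjusted = min(1, m * wt$p.value), method = "bonferroni")
  })
  new_test_report("kruskal", unname(kt$statistic),
                  c(unname(kt$parameter), NA), kt$p.value, pairwise = pw)
}

check_group_table <- function(y, g) {
  if (!all(is.finite(y))) abort("Metric values must be finite.",
                                class = "ripplepac_validation_error")
  if (nlevels(g) < 2) abort("At least 2 groups are required.",
                            class = "ripplepac_validation_error")
  if (any(tabulate(g) < 2)) {
    abort("Every group needs at least 2 values.",
          class = "ripplepac_validation_error")
  }
  invisible(TRUE)
}

new_test_report <- function(test, statistic, df, p_value,
                            pairwise = tibble()) {
  structure(list(test = test, statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value),
                 pairwise = pairwise),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic,
              paste(format(x$df, trim = TRUE), collapse = ", "), x$p_value))
  if (nrow(x$pairwise) > 0) print(x$pairwise)
  invisible(x)
}

#' Pairwise comparisons of a test report
#' @param x A `test_report`.
#' @param ... Unused.
#' @return The pairwise tibble.
#' @method tidy test_report
#' @export
tidy.test_report <- function(x, ...) x$pairwise

#' One-row summary of a test report
#' @param x A `test_report`.
#' @param ... Unused.
#' @return One-row tibble: test, statistic, df, p value.
#' @method glance test_report
#' @export
glance.test_report <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, df1 = x$df[1],
         df2 = x$df[2], p_value = x$p_value)
}

#' Group comparison report over one or more metrics
#'
#' For each metric: group means with SEM, a Levene variance check and
#' per-group Shapiro-Wilk normality checks, then routing to one-way
#' ANOVA + Scheffe (both checks pass) or Kruskal-Wallis + Bonferroni
#' (either fails), unless a route is forced. The routing rule and both
#' check p values are recorded in the output.
#'
#' @param data A data frame with one row per observation.
#' @param value,group Columns (tidy-eval) of values and group labels.
#' @param metric Optional column naming the metric each row belongs to;
#'   when given, one report row per metric is produced.
#' @param alpha Significance level for the routing checks (default 0.05).
#' @param route `"auto"` (default), or force `"anova"` / `"kruskal"`.
#' @return A tibble of class `group_report`: per metric, the route, the
#'   omnibus statistic/df/p, `levene_p`, `normality_p` (minimum across
#'   groups; `NA` when a group is too small to test), and list-columns
#'   `summary` (group, n, mean, sem) and `pairwise`.
#' @export
group_report <- function(data, value, group, metric = NULL, alpha = 0.05,
                         route = c("auto", "anova", "kruskal")) {
  route <- match.arg(route)
  metric_quo <- rlang::enquo(metric)
  df <- tibble(value = dplyr::pull(data, {{ value }}),
               group = as.character(dplyr::pull(data, {{ group }})))
  df$metric <- if (rlang::quo_is_null(metric_quo)) {
    "metric"
  } else {
    as.character(dplyr::pull(data, !!metric_quo))
  }

  out <- purrr::map_dfr(split(df, df$metric), function(d) {
    smry <- d |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                       .groups = "drop")
    lev <- levene_test(d, value, group)
    norm_p <- suppressWarnings(
      vapply(split(d$value, d$group), function(v) {
        if (length(v) >= 3 && length(v) <= 5000 && max(v) > min(v)) {
          shapiro.test(v)$p.value
        } else NA_real_
      }, numeric(1)))
    norm_min <- if (all(is.na(norm_p))) NA_real_ else min(norm_p, na.rm = TRUE)
    chosen <- if (route != "auto") {
      route
    } else if (lev$p_value < alpha ||
               (!is.na(norm_min) && norm_min < alpha)) {
      "kruskal"
    } else {
      "anova"
    }
    rep_ <- if (chosen == "anova") {
      anova_scheffe(d, value, group)
    } else {
      kruskal_bonferroni(d, value, group)
    }
    tibble(metric = d$metric[1], route = chosen,
           statistic = rep_$statistic, df1 = rep_$df[1], df2 = rep_$df[2],
           p_value = rep_$p_value, levene_p = lev$p_value,
           normality_p = norm_min,
           summary = list(smry), pairwise = list(rep_$pairwise))
  })
  class(out) <- c("group_report", class(out))
  out
}

#' Write a group report to JSON
#' @param report A [group_report()] tibble.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  lst <- purrr::map(seq_len(nrow(report)), function(i) {
    list(metric = report$metric[i], route = report$route[i],
         statistic = report$statistic[i],
         df = c(report$df1[i], report$df2[i]),
         p_value = report$p_value[i], levene_p = report$levene_p[i],
         normality_p = report$normality_p[i],
         groups = report$summary[[i]],
         pairwise = report$pairwise[[i]])
  })
  names(lst) <- report$metric
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
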