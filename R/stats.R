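# Statistical comparison layer: normality gating, omnibus group tests,
# post hoc pairwise t-tests, variance F-tests, regression R^2 and Lin's
# concordance correlation coefficient.

#' Shapiro-Wilk normality p-value
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return The Shapiro-Wilk p-value; `NA` (with a warning) for a constant
#'   sample, where normality is undefined.
#' @export
shapiro_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    rlang::abort("Shapiro test needs 3 <= n <= 5000",
                 class = "fsuaxial_error_stats")
  }
  if (stats::sd(x) == 0) {
    rlang::warn("normality undefined for a constant sample; reporting NA")
    return(NA_real_)
  }
  stats::shapiro.test(x)$p.value
}

#' Compare a metric between groups with normality gating
#'
#' Mirrors the study's testing logic: each group is screened with a
#' Shapiro-Wilk test at `alpha`; if every group passes, a one-way ANOVA is
#' used, otherwise a Kruskal-Wallis test. Post hoc pairwise t-tests
#' (unadjusted by default, optional Holm correction) are computed only after
#' a significant ANOVA; no post hoc follows a Kruskal-Wallis test.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the metric and the grouping
#'   factor.
#' @param alpha Significance level (default 0.05).
#' @param posthoc_adjust `"none"` (default) or `"holm"`.
#' @return An object of class `group_comparison`: `test_used` ("ANOVA" or
#'   "Kruskal-Wallis"), `omnibus_p`, `statistic`, `shapiro` (tibble of
#'   per-group p-values), `posthoc` (tibble of pairwise p-values or `NULL`),
#'   `significant`, `alpha`. Has a [generics::tidy()] method.
#' @export
compare_groups <- function(data, value, group, alpha = 0.05,
                           posthoc_adjust = c("none", "holm")) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  posthoc_adjust <- match.arg(posthoc_adjust)
  v <- data[[value]]
  g <- factor(data[[group]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  ng <- table(g)
  if (length(ng) < 2 || any(ng < 2)) {
    rlang::abort("need >= 2 groups with >= 2 observations each",
                 class = "fsuaxial_error_stats")
  }
  shapiro <- tibble::tibble(
    group = names(ng),
    p_normality = purrr::map_dbl(names(ng), function(k) {
      xi <- v[g == k]
      if (length(xi) < 3 || stats::sd(xi) == 0) NA_real_
      else stats::shapiro.test(xi)$p.value
    })
  )
  all_normal <- all(!is.na(shapiro$p_normality) &
                      shapiro$p_normality > alpha)
  if (all_normal) {
    fit <- stats::aov(v ~ g)
    tab <- summary(fit)[[1]]
    omnibus_p <- tab[["Pr(>F)"]][1]
    statistic <- tab[["F value"]][1]
    test_used <- "ANOVA"
  } else {
    kw <- stats::kruskal.test(v, g)
    omnibus_p <- kw$p.value
    statistic <- unname(kw$statistic)
    test_used <- "Kruskal-Wallis"
  }
  posthoc <- NULL
  if (test_used == "ANOVA" && !is.na(omnibus_p) && omnibus_p < alpha) {
    pw <- stats::pairwise.t.test(v, g, p.adjust.method = posthoc_adjust,
                                 pool.sd = FALSE)
    m <- pw$p.value
    posthoc <- tibble::as_tibble(as.data.frame(as.table(m)),
                                 .name_repair = "minimal")
    names(posthoc) <- c("group1", "group2", "p_value")
    posthoc <- posthoc[!is.na(posthoc$p_value), ]
    posthoc$group1 <- as.character(posthoc$group1)
    posthoc$group2 <- as.character(posthoc$group2)
  }
  structure(
    list(metric = value, test_used = test_used, omnibus_p = omnibus_p,
         statistic = statistic, shapiro = shapiro, posthoc = posthoc,
         significant = !is.na(omnibus_p) && omnibus_p < alpha,
         alpha = alpha, n = as.integer(length(v))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s: %s, p = %.4g%s\n", x$metric,
              x$test_used, x$omnibus_p,
              if (x$significant) " *" else ""))
  if (!is.null(x$posthoc)) {
    cat("Post hoc pairwise t-tests:\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus result.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, test_used = x$test_used,
                 statistic = x$statistic, omnibus_p = x$omnibus_p,
                 significant = x$significant, n = x$n)
}

#' Two-sided F-test for equality of variances
#'
#' `F = var(x) / var(y)` (sample variances) with the standard two-sided
#' p-value. Swapping the arguments inverts F and leaves p unchanged.
#'
#' @param x,y Numeric samples with n >= 2.
#' @return A one-row tibble with `f_statistic`, `p_value`, `df1`, `df2`.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("variance F-test needs n >= 2 in both samples",
                 class = "fsuaxial_error_stats")
  }
  vt <- stats::var.test(x, y)
  tibble::tibble(f_statistic = unname(vt$statistic),
                 p_value = vt$p.value,
                 df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2]))
}

#' Coefficient of determination of a simple linear regression
#'
#' R^2 of the ordinary least-squares regression of `y` on `x`.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return R^2 in `[0, 1]`.
#' @export
regression_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("regression needs equal-length samples with n >= 3",
                 class = "fsuaxial_error_stats")
  }
  summary(stats::lm(y ~ x))$r.squared
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' using population (1/n) moments by default (the original definition);
#' `type = "sample"` uses the unbiased (1/(n-1)) moments. Equals 1 iff
#' `y` is identical to `x`, and is bounded by the Pearson correlation in
#' magnitude.
#'
#' @param x,y Paired numeric vectors of equal length n >= 2, non-constant.
#' @param type Moment convention, `"population"` (default) or `"sample"`.
#' @return The concordance correlation coefficient, in `[-1, 1]`.
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 4, 6)) # 8/22
lin_ccc <- function(x, y, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (length(y) != n || n < 2) {
    rlang::abort("CCC needs paired samples of equal length >= 2",
                 class = "fsuaxial_error_stats")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("CCC undefined for constant inputs",
                 class = "fsuaxial_error_stats")
  }
  denom_n <- if (type == "population") n else n - 1
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / denom_n
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}
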