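#' Two-sample comparison through a normality-guided decision tree
#'
#' Compares two samples with the test chosen by a fixed routing rule, all
#' tests two-tailed at the same significance level `alpha`:
#'
#' 1. Shapiro-Wilk normality test on each sample.
#' 2. If both samples pass: F-test for equal variances, then a pooled-variance
#'    t-test (variances not rejected unequal) or a Welch t-test (rejected).
#' 3. If either fails normality: two-sample Kolmogorov-Smirnov test on the
#'    median-centered samples (a shape comparison that does not conflate
#'    location with shape), then a Wilcoxon rank-sum test (shape equality not
#'    rejected) or a Welch t-test (rejected).
#'
#' The Wilcoxon p-value is exact when the smaller sample has fewer than 25
#' observations and uses the continuity-corrected normal approximation
#' otherwise. The traversed path is recorded step by step.
#'
#' @param x,y Numeric samples, each with at least 4 values.
#' @param alpha Significance level for every test in the tree (default 0.01).
#' @return An object of class `tissue_test`: list with `path` (tibble of
#'   step, test, statistic, p_value), `final_test`, `final_p`, `reject`,
#'   `alpha`. `tidy()` returns the path; `glance()` the one-row outcome.
#' @examples
#' set.seed(1)
#' decision_tree_compare(rnorm(30), rnorm(30, 2))
#' @export
decision_tree_compare <- function(x, y, alpha = 0.01) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 4 || length(y) < 4) {
    abort("both samples need at least 4 values.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("samples must be finite.")
  if (sd(x) == 0 && sd(y) == 0) {
    abort("untestable: both samples have zero variance.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")

  steps <- list()
  add <- function(test, statistic, p) {
    steps[[length(steps) + 1]] <<- tibble(
      step = length(steps) + 1L, test = test,
      statistic = unname(statistic), p_value = unname(p)
    )
  }

  swx <- shapiro.test(x)
  add("shapiro_wilk_x", swx$statistic, swx$p.value)
  swy <- shapiro.test(y)
  add("shapiro_wilk_y", swy$statistic, swy$p.value)
  both_normal <- swx$p.value >= alpha && swy$p.value >= alpha

  if (both_normal) {
    ft <- var.test(x, y)
    add("f_variance", ft$statistic, ft$p.value)
    if (ft$p.value >= alpha) {
      tt <- t.test(x, y, var.equal = TRUE)
      add("t_pooled", tt$statistic, tt$p.value)
      final_test <- "t_pooled"
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      add("t_welch", tt$statistic, tt$p.value)
      final_test <- "t_welch"
    }
    final_p <- tt$p.value
  } else {
    ks <- suppressWarnings(ks.test(x - median(x), y - median(y)))
    add("ks_shape", ks$statistic, ks$p.value)
    if (ks$p.value >= alpha) {
      wt <- suppressWarnings(wilcox.test(
        x, y,
        exact = min(length(x), length(y)) < 25, correct = TRUE
      ))
      add("wilcoxon", wt$statistic, wt$p.value)
      final_test <- "wilcoxon"
      final_p <- wt$p.value
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      add("t_welch", tt$statistic, tt$p.value)
      final_test <- "t_welch"
      final_p <- tt$p.value
    }
  }

  structure(
    list(
      path = dplyr::bind_rows(steps),
      final_test = final_test,
      final_p = final_p,
      reject = final_p < alpha,
      alpha = alpha,
      n_x = length(x),
      n_y = length(y)
    ),
    class = "tissue_test"
  )
}

#' @export
print.tissue_test <- function(x, ...) {
  cat(sprintf("Decision-tree comparison (alpha = %g): %s, p = %.3g -> %s\n",
              x$alpha, x$final_test, x$final_p,
              if (x$reject) "reject" else "fail to reject"))
  print(x$path)
  invisible(x)
}

#' @rdname decision_tree_compare
#' @param x A `tissue_test` object.
#' @param ... Unused.
#' @method tidy tissue_test
#' @export
tidy.tissue_test <- function(x, ...) x$path

#' @rdname decision_tree_compare
#' @method glance tissue_test
#' @export
glance.tissue_test <- function(x, ...) {
  tibble(
    final_test = x$final_test, final_p = x$final_p,
    reject = x$reject, alpha = x$alpha, n_x = x$n_x, n_y = x$n_y
  )
}

#' Cohen's d standardized mean difference
#'
#' \eqn{d = |\bar x - \bar y| / s_p} with the pooled standard deviation
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}. Conventional
#' benchmarks: 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return The (nonnegative) effect size.
#' @examples
#' cohens_d(rnorm(50), rnorm(50, 1.4))
#' @export
cohens_d <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) abort("both samples need at least 2 values.")
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("undefined effect size: pooled variance is zero.")
  abs(mean(x) - mean(y)) / sqrt(sp2)
}

#' Run every property x rate comparison between two tissues
#'
#' The univariate driver: for each of the five mechanical properties and each
#' loading rate present in the table, runs [decision_tree_compare()] between
#' the two tissue groups and computes Cohen's d. No multiple-testing
#' correction is applied (each comparison is reported at its own `alpha`).
#'
#' @param properties A property table (after outlier removal), with columns
#'   `tissue`, `rate_mm_s` and the five property columns.
#' @param alpha Significance level (default 0.01).
#' @param tissues Character vector of the two tissue labels to compare;
#'   defaults to the two labels present (first = x group).
#' @return A tibble with one row per property x rate: `property`,
#'   `rate_mm_s`, `n_x`, `n_y`, `final_test`, `final_p`, `reject`,
#'   `cohens_d`. The full decision paths are attached as the `"paths"`
#'   attribute (a named list of `tissue_test` objects).
#' @export
compare_properties <- function(properties, alpha = 0.01, tissues = NULL) {
  if (is.null(tissues)) {
    tissues <- unique(properties$tissue)
  }
  if (length(tissues) != 2) {
    abort("`properties` must contain exactly two tissue labels.")
  }
  grid <- tidyr::expand_grid(
    property = property_cols(),
    rate_mm_s = sort(unique(properties$rate_mm_s))
  )
  paths <- list()
  out <- purrr::pmap(grid, function(property, rate_mm_s) {
    sub <- properties[properties$rate_mm_s == rate_mm_s, ]
    x <- sub[[property]][sub$tissue == tissues[1]]
    y <- sub[[property]][sub$tissue == tissues[2]]
    res <- decision_tree_compare(x, y, alpha = alpha)
    paths[[paste(property, rate_mm_s, sep = "@")]] <<- res
    tibble(
      property = property, rate_mm_s = rate_mm_s,
      n_x = length(x), n_y = length(y),
      final_test = res$final_test, final_p = res$final_p,
      reject = res$reject, cohens_d = cohens_d(x, y)
    )
  }) |>
    dplyr::bind_rows()
  attr(out, "paths") <- paths
  attr(out, "alpha") <- alpha
  out
}
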