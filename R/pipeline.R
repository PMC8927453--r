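#' Configure an end-to-end study run
#'
#' Collects every constant the pipeline uses in one place so that a report is
#' reproducible from its config and seed alone: the generator populations,
#' curve resolution, significance level, target power and allocation ratio
#' for the sample-size block, and the fit options.
#'
#' @param populations Generator population table ([default_populations()]);
#'   ignored when `run_pipeline()` is given user curves.
#' @param n_points Grid points per synthetic curve.
#' @param seed Master seed.
#' @param alpha Significance level for every univariate test (default 0.01).
#' @param power Target power for the sample-size block (default 0.99).
#' @param allocation_ratio Planned `n_large / n_small` (default 2.5).
#' @param lambda Ridge stabilizer for the classifier.
#' @param positive Positive class label.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(populations = default_populations(),
                            n_points = 200, seed = 1L,
                            alpha = 0.01, power = 0.99,
                            allocation_ratio = 2.5,
                            lambda = 1e-4, positive = "human") {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(
      populations = populations, n_points = n_points, seed = as.integer(seed),
      alpha = alpha, power = power, allocation_ratio = allocation_ratio,
      lambda = lambda, positive = positive
    ),
    class = "pipeline_config"
  )
}

#' Run the whole comparison pipeline
#'
#' Executes, in order: synthetic study generation (skipped when `curves` and
#' `meta` are supplied), property extraction, extreme-outlier removal,
#' the univariate decision-tree comparisons (five properties x each rate),
#' the effect-size and sample-size block, and LOOCV logistic classification
#' per rate plus rate-combined. Identical config and seed give an identical
#' report.
#'
#' @param config A [pipeline_config()].
#' @param curves,meta Optional user-supplied tables (see
#'   [extract_properties()]); when given, the generator stage is skipped.
#' @return A list of class `study_report` with elements `properties`,
#'   `outliers`, `univariate` (one row per property x rate), `effect_size`
#'   (headline pooled d plus the sample-size calculation), `classification`
#'   (list of `tissue_classifier`, one per rate plus `"combined"`),
#'   `classification_summary` (tibble, one row per task), `config`.
#' @examples
#' cfg <- pipeline_config(default_populations() |> dplyr::mutate(n_samples = 6L),
#'                        seed = 11)
#' report <- run_pipeline(cfg)
#' @export
run_pipeline <- function(config = pipeline_config(), curves = NULL, meta = NULL) {
  if (is.null(curves) != is.null(meta)) {
    abort("supply both `curves` and `meta`, or neither.")
  }
  if (is.null(curves)) {
    study <- generate_study(config$populations, n_points = config$n_points,
                            seed = config$seed)
    curves <- study$curves
    meta <- study$meta
  }

  properties <- extract_properties(curves, meta)
  filtered <- remove_outliers(properties)
  kept <- filtered$kept

  univariate <- compare_properties(kept, alpha = config$alpha)

  pooled_d <- mean(univariate$cohens_d)
  sizes <- required_sample_sizes(
    d = pooled_d, alpha = config$alpha, power = config$power,
    ratio = config$allocation_ratio
  )
  effect_size <- list(
    per_comparison = univariate[c("property", "rate_mm_s", "cohens_d")],
    pooled_d = pooled_d,
    sample_size = sizes
  )

  rates <- sort(unique(kept$rate_mm_s))
  classification <- purrr::map(rates, function(r) {
    loocv_classify(kept[kept$rate_mm_s == r, ], lambda = config$lambda,
                   positive = config$positive, task_label = as.character(r))
  })
  names(classification) <- as.character(rates)
  classification$combined <- loocv_classify(
    combine_rates(purrr::map(rates, function(r) kept[kept$rate_mm_s == r, ])),
    lambda = config$lambda, positive = config$positive, task_label = "combined"
  )

  structure(
    list(
      properties = properties,
      outliers = filtered$removed,
      univariate = univariate,
      effect_size = effect_size,
      classification = classification,
      classification_summary = purrr::map(classification, glance) |>
        dplyr::bind_rows(),
      config = config
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d specimens (%d removed as outliers), alpha = %g\n",
              nrow(x$properties), nrow(x$outliers), x$config$alpha))
  cat(sprintf("Univariate: %d/%d comparisons reject; pooled Cohen's d = %.2f\n",
              sum(x$univariate$reject), nrow(x$univariate),
              x$effect_size$pooled_d))
  cat(sprintf("Required group sizes at d = %.2f: %d / %d (%s convention)\n",
              x$effect_size$pooled_d, x$effect_size$sample_size$n_small,
              x$effect_size$sample_size$n_large,
              x$effect_size$sample_size$convention))
  cat("Classification (LOOCV logistic regression):\n")
  print(x$classification_summary)
  invisible(x)
}

#' Read tensile-test tables from delimited text
#'
#' `read_curves()` expects columns `sample_id`, `displacement_mm`, `force_N`;
#' `read_meta()` expects `sample_id`, `tissue`, `rate_mm_s`, `L0_mm`,
#' `A0_mm2`; `read_properties()` expects the property-table schema. A missing
#' required column raises an error naming it; malformed rows surface through
#' readr's line-numbered parse problems; an empty file returns an empty
#' tibble with a warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the validated schema.
#' @export
read_curves <- function(path) {
  read_checked(path, c("sample_id", "displacement_mm", "force_N"))
}

#' @rdname read_curves
#' @export
read_meta <- function(path) {
  read_checked(path, c("sample_id", "tissue", "rate_mm_s", "L0_mm", "A0_mm2"))
}

#' @rdname read_curves
#' @export
read_properties <- function(path) {
  read_checked(path, c("sample_id", "tissue", "rate_mm_s", property_cols()))
}

read_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    warn(sprintf("empty file: %s", path))
    return(as_tibble(setNames(rep(list(logical(0)), length(required)), required)))
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse problems in %s (first at row %d: %s)",
                  path, probs$row[1], probs$expected[1]))
  }
  df
}

#' Serialize a study report to structured text (JSON)
#'
#' Writes the univariate table, effect-size block, outlier log, per-task
#' confusion matrices and metric suites, and the config constants. Numeric
#' values are written at full precision so a written report can be compared
#' across runs.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  payload <- list(
    seed = report$config$seed,
    alpha = report$config$alpha,
    n_specimens = nrow(report$properties),
    outliers_removed = report$outliers,
    univariate = report$univariate,
    pooled_cohens_d = report$effect_size$pooled_d,
    sample_size = report$effect_size$sample_size,
    classification = purrr::map(report$classification, function(cl) {
      list(
        task = cl$task_label,
        confusion = cl$confusion,
        metrics = cl$metrics,
        contributions = cl$contributions
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
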