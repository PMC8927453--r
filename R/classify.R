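# Ridge-stabilized logistic regression by iteratively reweighted least
# squares. X is the raw design (no intercept column); features are expected
# standardized by the caller. The intercept is unpenalized; lambda penalizes
# (lambda/2) * sum(beta_j^2). Near-separable data stay bounded for any
# lambda > 0, which is why the weak penalty exists at all.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  X1 <- cbind(`(intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    hess <- crossprod(X1, X1 * w) + pen
    step <- drop(solve(hess, grad))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = drop(beta), iterations = it, converged = max(abs(step)) < tol)
}

predict_ridge <- function(fit, X) {
  eta <- drop(cbind(1, X) %*% fit$beta)
  1 / (1 + exp(-eta))
}

standardize_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Leave-one-out cross-validated logistic classification of tissue type
#'
#' For each specimen in turn, the remaining specimens are standardized (mean
#' 0, SD 1, statistics from the training rows only, so no information leaks
#' into the held-out specimen), a ridge-stabilized logistic regression is
#' fitted, and the held-out specimen's class probability is recorded. Labels
#' are assigned at probability threshold 0.5 with `positive` as the positive
#' class; the confusion matrix, the eight-metric suite (accuracy,
#' sensitivity, specificity, F1, ROC-AUC, MCC, FMI, ARI) and per-feature
#' contribution shares (from a full-data standardized fit) are assembled from
#' the pooled out-of-fold results. The procedure has no stochastic step: the
#' same table always yields the same report.
#'
#' @param data A tibble with a `tissue` column and the feature columns.
#' @param features Character vector of feature columns; defaults to the five
#'   mechanical properties.
#' @param positive Positive-class label (default `"human"`).
#' @param lambda Ridge penalty on standardized coefficients (default 1e-4,
#'   a numerical stabilizer, not a tuning parameter).
#' @param contributions_lambda Ridge penalty for the contribution analysis
#'   only (default 1). The stress-derived features are nearly collinear, so
#'   the near-unpenalized coefficients that classify well have unstable,
#'   sign-cancelling magnitudes; a unit-strength ridge yields a stable,
#'   correlation-tempered importance ranking. This is an interpretive choice
#'   (the contribution analysis has no canonical definition) and is recorded
#'   in the report.
#' @param task_label Label stored in the report (e.g. the loading rate).
#' @return An object of class `tissue_classifier`: list with `confusion`
#'   (tibble tp/fp/fn/tn), `metrics` (one-row tibble of the eight metrics),
#'   `oof` (per-sample out-of-fold probabilities and predictions),
#'   `contributions` (per-feature shares summing to 1), `task_label`,
#'   `positive`. `tidy()` returns the metrics in long form, `glance()` the
#'   one-row metric tibble, `augment()` the out-of-fold table.
#' @examples
#' pops <- default_populations() |> dplyr::mutate(n_samples = 8L)
#' study <- generate_study(pops, seed = 2)
#' props <- extract_properties(study$curves, study$meta)
#' loocv_classify(props)
#' @export
loocv_classify <- function(data, features = property_cols(),
                           positive = "human", lambda = 1e-4,
                           contributions_lambda = 1,
                           task_label = "combined") {
  if (!"tissue" %in% names(data)) abort("`data` must have a `tissue` column.")
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[features])
  if (any(!is.finite(X))) abort("features must be finite.")
  y <- as.integer(data$tissue == positive)
  n <- length(y)
  if (n < 10) abort("need at least 10 specimens.")
  if (length(unique(y)) < 2) {
    abort("invalid task: both classes must be present.")
  }

  oof_prob <- vapply(seq_len(n), function(i) {
    tr <- standardize_train(X[-i, , drop = FALSE])
    fit <- ridge_logistic(tr$X, y[-i], lambda = lambda)
    xs <- (X[i, ] - tr$center) / tr$scale
    predict_ridge(fit, matrix(xs, nrow = 1))
  }, numeric(1))
  pred <- as.integer(oof_prob > 0.5)

  confusion <- tibble(
    tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
    fn = sum(pred == 0 & y == 1), tn = sum(pred == 0 & y == 0)
  )
  metrics <- compute_metrics(confusion, oof_prob, y)

  full <- standardize_train(X)
  full_fit <- ridge_logistic(full$X, y, lambda = contributions_lambda)
  beta_std <- full_fit$beta[-1]
  contributions <- tibble(
    feature = features,
    share = abs(beta_std) / sum(abs(beta_std)),
    coefficient = beta_std,
    reliable = full_fit$converged && sum(abs(beta_std)) > 0
  )

  structure(
    list(
      task_label = task_label,
      positive = positive,
      confusion = confusion,
      metrics = metrics,
      oof = tibble(
        sample_id = if ("sample_id" %in% names(data)) data$sample_id
                    else as.character(seq_len(n)),
        truth = y, probability = oof_prob, predicted = pred
      ),
      contributions = contributions
    ),
    class = "tissue_classifier"
  )
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat(sprintf("LOOCV logistic classification [%s], positive class \"%s\"\n",
              x$task_label, x$positive))
  cat(sprintf("  confusion: tp=%d fp=%d fn=%d tn=%d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$fn, x$confusion$tn))
  print(x$metrics)
  invisible(x)
}

#' @rdname loocv_classify
#' @param x A `tissue_classifier` object.
#' @param ... Unused.
#' @method tidy tissue_classifier
#' @export
tidy.tissue_classifier <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname loocv_classify
#' @method glance tissue_classifier
#' @export
glance.tissue_classifier <- function(x, ...) {
  dplyr::bind_cols(tibble(task_label = x$task_label), x$confusion, x$metrics)
}

#' @rdname loocv_classify
#' @method augment tissue_classifier
#' @export
augment.tissue_classifier <- function(x, ...) x$oof

#' Concatenate per-rate property tables into one rate-independent task
#'
#' Row-binds the tables; loading rate is deliberately NOT carried as a
#' feature (the combined task asks whether tissue type is separable
#' regardless of rate). All tables must share the same columns in the same
#' order.
#'
#' @param ... Two or more property tables (or a single list of them).
#' @return One tibble with all rows.
#' @export
combine_rates <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) < 2) abort("need at least 2 tables to combine.")
  cols <- names(tables[[1]])
  for (i in seq_along(tables)[-1]) {
    if (!identical(names(tables[[i]]), cols)) {
      abort(sprintf("schema mismatch: table %d has different columns or order.", i))
    }
  }
  dplyr::bind_rows(tables)
}
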