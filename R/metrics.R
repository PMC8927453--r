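# choose-2 helper for pair-counting indices
choose2 <- function(n) n * (n - 1) / 2

#' Classification performance metrics from a 2x2 confusion matrix
#'
#' Computes the eight-metric suite from the confusion counts and the pooled
#' out-of-fold probabilities:
#' accuracy `(tp+tn)/n`; sensitivity `tp/(tp+fn)`; specificity `tn/(tn+fp)`;
#' F1 `2tp/(2tp+fp+fn)`; MCC (Matthews correlation coefficient);
#' FMI (Fowlkes-Mallows index, the geometric mean of precision and
#' sensitivity); ARI (adjusted Rand index of the predicted vs. true
#' two-block partitions, pair-counting form); and ROC-AUC, the
#' Mann-Whitney probability that a random positive scores above a random
#' negative (ties counted half).
#'
#' A metric whose denominator vanishes is reported as `NA` with a warning
#' rather than silently coerced to 0. If `probabilities` is `NULL`, ROC-AUC
#' is `NA`.
#'
#' @param confusion A one-row data frame (or named list) with counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @param probabilities Out-of-fold positive-class probabilities (optional).
#' @param truth 0/1 truth labels aligned with `probabilities`.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `roc_auc`, `mcc`, `fmi`, `ari`.
#' @examples
#' compute_metrics(tibble::tibble(tp = 95, fp = 2, fn = 2, tn = 36))
#' @export
compute_metrics <- function(confusion, probabilities = NULL, truth = NULL) {
  tp <- confusion$tp
  fp <- confusion$fp
  fn <- confusion$fn
  tn <- confusion$tn
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be nonnegative integers.")
  }
  n <- tp + fp + fn + tn

  safe_div <- function(num, den, name) {
    if (den == 0) {
      warn(sprintf("%s is undefined (zero denominator); reported as NA.", name))
      return(NA_real_)
    }
    num / den
  }

  accuracy <- safe_div(tp + tn, n, "accuracy")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "f1")
  ppv <- safe_div(tp, tp + fp, "precision (for FMI)")

  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warn("mcc is undefined (zero denominator); reported as NA.")
    NA_real_
  } else {
    (tp * tn - fp * fn) / mcc_den
  }

  fmi <- if (is.na(ppv) || is.na(sensitivity)) NA_real_ else sqrt(ppv * sensitivity)
  ari <- adjusted_rand_2x2(tp, fp, fn, tn)

  roc_auc <- if (!is.null(probabilities) && !is.null(truth)) {
    roc_auc_rank(probabilities, truth)
  } else {
    NA_real_
  }

  tibble(
    accuracy = accuracy, sensitivity = sensitivity, specificity = specificity,
    f1 = f1, roc_auc = roc_auc, mcc = mcc, fmi = fmi, ari = ari
  )
}

#' Adjusted Rand index of the two-block partitions behind a confusion matrix
#'
#' Treats predicted and true labels as two 2-block partitions of the same
#' `n` samples and applies the chance-corrected pair-counting formula:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return The ARI in `[-1, 1]`; `NA` (with warning) when the index is
#'   undefined (fewer than 2 samples or both partitions trivial).
#' @export
adjusted_rand_2x2 <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  if (n < 2) {
    warn("ari is undefined for fewer than 2 samples; reported as NA.")
    return(NA_real_)
  }
  sum_ij <- choose2(tp) + choose2(fp) + choose2(fn) + choose2(tn)
  a <- c(tp + fn, fp + tn)          # true-class sizes
  b <- c(tp + fp, fn + tn)          # predicted-class sizes
  expected <- sum(choose2(a)) * sum(choose2(b)) / choose2(n)
  max_index <- (sum(choose2(a)) + sum(choose2(b))) / 2
  if (max_index == expected) {
    # both partitions trivial (single block): Rand index is 1 by convention
    # when the partitions agree, undefined otherwise; here they must agree
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' ROC-AUC from pooled scores by the rank (Mann-Whitney) method
#'
#' @param scores Positive-class scores.
#' @param truth 0/1 labels.
#' @return The AUC; `NA` with a warning if either class is absent.
#' @export
roc_auc_rank <- function(scores, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    warn("roc_auc is undefined with a single class; reported as NA.")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
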