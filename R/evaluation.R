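# Performance metrics, the analytic chance threshold, the predictive-value
# screen, and the label-permutation significance test.

#' Classification accuracy
#'
#' The proportion of correctly classified subjects over the LOOCV folds,
#' `(TP + TN) / N`, with converters (`"C"`) as the positive class.
#'
#' @param result A `tract_clf_result`, or a character vector of true labels.
#' @param predicted When `result` is a label vector, the predicted labels.
#' @return Proportion in [0, 1].
#' @export
accuracy <- function(result, predicted = NULL) {
  if (inherits(result, "tract_clf_result")) {
    truth <- result$fold_records$truth
    predicted <- result$fold_records$predicted
  } else truth <- result
  if (length(truth) == 0L) stopf("no fold records")
  mean(truth == predicted)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC computed from the pooled LOOCV decision
#' scores, with `"C"` as the positive class; tied scores contribute 1/2.
#'
#' @param result A `tract_clf_result`, or a character vector of true labels.
#' @param score When `result` is a label vector, the decision scores.
#' @return Area in [0, 1].
#' @export
auc <- function(result, score = NULL) {
  if (inherits(result, "tract_clf_result")) {
    truth <- result$fold_records$truth
    score <- result$fold_records$score
  } else truth <- result
  pos <- truth == "C"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes required to compute AUC")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Chance-level accuracy threshold
#'
#' The smallest two-decimal accuracy `t` such that a random classifier on
#' `n` subjects exceeds `t` with probability at most `alpha`, under an exact
#' Binomial(n, 1/2) model of chance performance:
#' `P(X/n > t) <= alpha`. For the 87-subject study design this gives 0.59
#' at `alpha = 0.05`.
#'
#' @param n Number of classified subjects.
#' @param alpha Significance level (default 0.05).
#' @return Accuracy threshold rounded to two decimals.
#' @export
#' @examples
#' chance_threshold(87, 0.05) # 0.59
chance_threshold <- function(n, alpha = 0.05) {
  n <- assert_scalar_count(n, "n", 1L)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be in (0, 1)")
  for (t in seq(0, 1, by = 0.01)) {
    # P(X > t * n) = P(X >= floor(t n) + 1)
    p <- pbinom(floor(t * n + 1e-9), n, 0.5, lower.tail = FALSE)
    if (p <= alpha) return(round(t, 2))
  }
  1
}

#' Screen classifiers for predictive value
#'
#' Keeps the tract/property classifiers whose accuracy strictly exceeds the
#' chance threshold and whose AUC strictly exceeds `auc_floor`; both
#' conditions must hold (a classifier with accuracy 0.60 but AUC 0.35 is
#' excluded).
#'
#' @param results A list of `tract_clf_result` objects, or a data frame
#'   with columns `tract_id`, `property`, `accuracy`, `auc`.
#' @param acc_threshold Accuracy threshold; defaults to
#'   `chance_threshold(n)` of the first result.
#' @param auc_floor AUC floor (default 0.6).
#' @param alpha Significance level for the default accuracy threshold.
#' @return A tibble of all screened classifiers with a logical `predictive`
#'   column; the screen parameters are attached as attributes.
#' @export
screen_predictive <- function(results, acc_threshold = NULL, auc_floor = 0.6,
                              alpha = 0.05) {
  if (inherits(results, "tract_clf_result")) results <- list(results)
  if (is.data.frame(results)) {
    tbl <- tibble::as_tibble(results)
    if (is.null(acc_threshold)) stopf("supply `acc_threshold` with a data frame")
  } else {
    tbl <- tibble::tibble(
      tract_id = vapply(results, `[[`, "", "tract_id", USE.NAMES = FALSE),
      property = vapply(results, `[[`, "", "property", USE.NAMES = FALSE),
      accuracy = vapply(results, `[[`, 1, "accuracy", USE.NAMES = FALSE),
      auc = vapply(results, `[[`, 1, "auc", USE.NAMES = FALSE))
    if (is.null(acc_threshold))
      acc_threshold <- chance_threshold(results[[1]]$n, alpha)
  }
  tbl$predictive <- tbl$accuracy > acc_threshold & tbl$auc > auc_floor
  attr(tbl, "acc_threshold") <- acc_threshold
  attr(tbl, "auc_floor") <- auc_floor
  tbl
}

#' Permutation test of classifier accuracy
#'
#' Re-runs the complete LOOCV pipeline (fold-wise normalization, RFE-CBR,
#' SVM training and prediction) on `n_perm` cohorts whose group labels are
#' randomly permuted while preserving the original class counts, building a
#' null distribution of accuracies. Two p-values are returned: the
#' one-sample t-test comparing the observed accuracy against the null
#' distribution, and the empirical permutation p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. The empirical p-value is
#' the preferred summary: the t-test treats the null draws as the sample
#' and is anti-conservative.
#'
#' @param cohort A [tract_cohort()].
#' @param tract_id,property Classifier to test.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed governing all shuffles.
#' @param observed Optional precomputed `tract_clf_result` for the
#'   unpermuted labels (avoids recomputation).
#' @param ... Passed to [loocv_classify()].
#' @return An object of class `permutation_result`: `null_accuracies`,
#'   `observed_accuracy`, `t_test_p`, `empirical_p`, `n_perm`.
#' @export
permutation_test <- function(cohort, tract_id, property, n_perm = 1000L,
                             seed = 1L, observed = NULL, ...) {
  n_perm <- assert_scalar_count(n_perm, "n_perm", 1L)
  if (is.null(observed))
    observed <- loocv_classify(cohort, tract_id, property, ...)
  fm <- feature_matrix(cohort, tract_id, property)
  dots <- list(...)
  null_acc <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yb <- sample(fm$y)
    cv <- do.call(loocv_matrix, c(list(x = fm$x, y = yb), dots))
    mean(yb == cv$pred)
  }, 1))
  obs <- observed$accuracy
  tt <- t.test(null_acc, mu = obs)
  structure(list(tract_id = tract_id, property = property,
                 null_accuracies = null_acc, observed_accuracy = obs,
                 t_test_p = tt$p.value,
                 empirical_p = (1 + sum(null_acc >= obs)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> %s / %s: observed %.3f vs null ",
                     "%.3f (sd %.3f, %d perms)\n  empirical p = %.4g, ",
                     "t-test p = %.4g\n"),
              x$tract_id, x$property, x$observed_accuracy,
              mean(x$null_accuracies), sd(x$null_accuracies), x$n_perm,
              x$empirical_p, x$t_test_p))
  invisible(x)
}
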