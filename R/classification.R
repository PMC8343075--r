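# Nested LOOCV classification engine: fold-wise normalization, SVM-RFE with
# correlation-bias reduction, RBF-SVM training and prediction.

#' Fit and apply per-feature normalization
#'
#' Normalization parameters (per-feature mean and sample SD, n-1
#' denominator) are estimated on training rows only and then applied as a
#' fixed affine transform, so the held-out subject never contributes to the
#' statistics.
#'
#' @param x Numeric matrix, rows = subjects, columns = features.
#' @return `normalize_fit()` returns an object of class `norm_params`;
#'   `normalize_apply()` the transformed matrix.
#' @export
normalize_fit <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L) stopf("need a matrix with >= 2 rows")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  if (any(sdev <= 0)) {
    bad <- colnames(x)[sdev <= 0] %||% which(sdev <= 0)
    stopf("constant feature(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev, features = colnames(x)),
            class = "norm_params")
}

#' @rdname normalize_fit
#' @param params A `norm_params` object from `normalize_fit()`.
#' @export
normalize_apply <- function(params, x) {
  if (!inherits(params, "norm_params")) stopf("`params` must be norm_params")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(params$mean))
    stopf("feature count mismatch: %d vs %d", ncol(x), length(params$mean))
  if (!is.null(params$features) && !is.null(colnames(x)) &&
      !identical(colnames(x), params$features))
    stopf("feature names do not match normalization parameters")
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}

labels_to_pm1 <- function(y) {
  y <- as.character(y)
  if (!all(y %in% c("C", "NC"))) stopf("labels must be 'C' or 'NC'")
  ifelse(y == "C", 1L, -1L)
}

default_gamma <- function(x) {
  v <- mean(apply(x, 2, var))
  if (v <= 0) stopf("zero pooled feature variance")
  1 / (ncol(x) * v)
}

#' Train a radial-basis-function SVM
#'
#' Soft-margin C-SVC with RBF kernel `exp(-gamma * ||u - v||^2)`, solved by
#' the package's compiled SMO solver. The decision score is positive for
#' the converter class `"C"`. By default `gamma = 1 / (n_features * pooled
#' feature variance)` and `cost = 1`; no inner tuning loop is performed.
#'
#' @param x Numeric training matrix (rows = subjects).
#' @param y Labels, `"C"`/`"NC"`; both classes must be present.
#' @param cost Regularization constant C.
#' @param gamma RBF kernel width; `NULL` for the default above.
#' @param tol SMO convergence tolerance.
#' @return An object of class `rbf_svm` with a [predict.rbf_svm()] method.
#' @export
train_svm <- function(x, y, cost = 1, gamma = NULL, tol = 1e-3) {
  x <- as.matrix(x)
  ypm <- labels_to_pm1(y)
  if (length(unique(ypm)) < 2L) stopf("training data contain a single class")
  if (is.null(gamma)) gamma <- default_gamma(x)
  fit <- .svm_rbf_train_cpp(x, ypm, cost, gamma, tol, 100000L)
  structure(list(x = x, coefs = as.numeric(fit$coefs), b = fit$b,
                 gamma = gamma, cost = cost),
            class = "rbf_svm")
}

#' Predict from an RBF SVM
#'
#' @param object An `rbf_svm` model.
#' @param newdata Numeric matrix (or single row) of observations.
#' @param type `"class"` for `"C"`/`"NC"` labels, `"decision"` for raw
#'   decision scores (positive = `"C"`).
#' @param ... Unused.
#' @export
predict.rbf_svm <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  f <- .svm_rbf_decision_cpp(object$x, object$coefs, object$b,
                             object$gamma, newdata)
  if (type == "decision") f else ifelse(f > 0, "C", "NC")
}

# Greedy clique grouping of features by absolute Pearson correlation
# (R mirror of the compiled engine's grouping; used for reporting/tests).
correlation_groups <- function(x, corr_threshold = 0.9) {
  r <- abs(cor(x))
  groups <- list()
  for (f in seq_len(ncol(x))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(r[f, groups[[g]]] >= corr_threshold)) {
        groups[[g]] <- c(groups[[g]], f); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- f
  }
  groups
}

#' SVM recursive feature elimination with correlation-bias reduction
#'
#' Eliminates one feature per iteration until `target_k` remain. At each
#' iteration an RBF-SVM is fitted to the remaining features and every
#' feature (group) is scored by the decrease in the SVM objective when its
#' kernel contribution is removed with the dual coefficients held fixed:
#' `dJ = 1/2 a'Ha - 1/2 a'H^(-i)a`. Correlation-bias reduction scores
#' highly correlated features (greedy cliques with pairwise `|r| >=
#' corr_threshold` on training data) by removing the whole group and
#' assigning the group score to each member, preventing correlated features
#' from masking one another's relevance. Ties keep the lower feature index.
#'
#' @param x Numeric training matrix.
#' @param y Labels `"C"`/`"NC"`.
#' @param cost SVM regularization constant.
#' @param target_k Number of features to retain (default 10).
#' @param corr_threshold Correlation-group threshold (default 0.9).
#' @param use_cbr Set `FALSE` for plain SVM-RFE without grouping.
#' @param tol SMO convergence tolerance.
#' @return List with `selected` (sorted indices of retained features),
#'   `ranking` (all features, worst to best: elimination order followed by
#'   the survivors) and `elim_order`.
#' @export
rfe_cbr <- function(x, y, cost = 1, target_k = 10L, corr_threshold = 0.9,
                    use_cbr = TRUE, tol = 1e-3) {
  x <- as.matrix(x)
  ypm <- labels_to_pm1(y)
  if (length(unique(ypm)) < 2L) stopf("training data contain a single class")
  target_k <- min(assert_scalar_count(target_k, "target_k", 1L), ncol(x))
  res <- .rfe_svm_engine_cpp(x, ypm, matrix(0, 0L, ncol(x)), cost,
                             target_k, corr_threshold, use_cbr, tol, 100000L)
  selected <- sort(as.integer(res$selected))
  list(selected = selected,
       ranking = c(as.integer(res$elim_order), selected),
       elim_order = as.integer(res$elim_order))
}

# Shared LOOCV core on a plain feature matrix. Returns one record per row:
# fold-wise normalization fitted on the N-1 training rows, RFE-CBR on the
# training rows only, RBF-SVM on the selected features, decision score for
# the held-out row.
loocv_matrix <- function(x, y, cost = 1, target_k = 10L,
                         corr_threshold = 0.9, use_cbr = TRUE, tol = 1e-3) {
  n <- nrow(x)
  ypm <- labels_to_pm1(y)
  if (sum(ypm == 1L) < 2L || sum(ypm == -1L) < 2L)
    stopf("need >= 2 subjects per class")
  k <- min(target_k, ncol(x))
  pred <- character(n); score <- numeric(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    params <- normalize_fit(x[-i, , drop = FALSE])
    xtr <- normalize_apply(params, x[-i, , drop = FALSE])
    xte <- normalize_apply(params, x[i, , drop = FALSE])
    res <- .rfe_svm_engine_cpp(xtr, ypm[-i], xte, cost, k,
                               corr_threshold, use_cbr, tol, 100000L)
    selected[[i]] <- sort(as.integer(res$selected))
    score[i] <- res$decision[1]
    pred[i] <- if (res$decision[1] > 0) "C" else "NC"
  }
  list(pred = pred, score = score, selected = selected)
}

#' Leave-one-out cross-validated tract classification
#'
#' For each subject in turn: normalization is fitted on the remaining N-1
#' subjects, both partitions are transformed, recursive feature elimination
#' (with correlation-bias reduction) reduces the training features to the
#' `target_k` most discriminative tract nodes, an RBF-SVM is trained on
#' those nodes, and the left-out subject is classified. The held-out
#' subject never enters normalization statistics, correlation estimates,
#' feature ranking or SVM fitting.
#'
#' @param cohort A [tract_cohort()] with >= 2 subjects per class.
#' @param tract_id Tract to classify on.
#' @param property `"FA"`, `"MD"`, `"RD"`, `"AxD"`, or `"ALL"` for the
#'   concatenated four-property feature set.
#' @param cost,target_k,corr_threshold,use_cbr,tol Passed to the engine;
#'   see [rfe_cbr()] and [train_svm()].
#' @return An object of class `tract_clf_result`: per-fold records
#'   (predicted label, decision score, selected nodes), pooled `accuracy`
#'   and `auc`, and the feature map.
#' @export
#' @seealso [accuracy()], [auc()], [selection_histogram()]
loocv_classify <- function(cohort, tract_id, property, cost = 1,
                           target_k = 10L, corr_threshold = 0.9,
                           use_cbr = TRUE, tol = 1e-3) {
  fm <- feature_matrix(cohort, tract_id, property)
  cv <- loocv_matrix(fm$x, fm$y, cost = cost, target_k = target_k,
                     corr_threshold = corr_threshold, use_cbr = use_cbr,
                     tol = tol)
  fold_records <- tibble::tibble(
    subject_id = cohort$subjects$subject_id,
    truth = fm$y, predicted = cv$pred, score = cv$score,
    selected = cv$selected)
  res <- structure(list(tract_id = tract_id, property = property,
                        fold_records = fold_records, features = fm$features,
                        n = nrow(fm$x), n_nodes = cohort$n_nodes,
                        settings = list(cost = cost, target_k = target_k,
                                        corr_threshold = corr_threshold,
                                        use_cbr = use_cbr)),
                   class = "tract_clf_result")
  res$accuracy <- accuracy(res)
  res$auc <- auc(res)
  res
}

#' @export
print.tract_clf_result <- function(x, ...) {
  cat(sprintf("<tract_clf_result> %s / %s: n = %d, accuracy = %.3f, AUC = %.3f\n",
              x$tract_id, x$property, x$n, x$accuracy, x$auc))
  invisible(x)
}
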