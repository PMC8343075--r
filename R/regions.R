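# Node-selection stability, FDR-tested group differences at selected nodes,
# predictive-region definition, and the final region-restricted classifier.

#' Node-selection histogram across LOOCV folds
#'
#' The fraction of LOOCV folds in which each feature (tract node) was
#' retained by the RFE procedure. Stable selection across folds indicates
#' that a node's discriminative value does not hinge on any single subject.
#'
#' @param result A `tract_clf_result` from [loocv_classify()].
#' @return An object of class `selection_histogram`: a tibble with one row
#'   per feature (`tract_id`, `property`, `node`, `count`, `freq`).
#' @export
selection_histogram <- function(result) {
  if (!inherits(result, "tract_clf_result"))
    stopf("`result` must be a tract_clf_result")
  n_feat <- nrow(result$features)
  counts <- tabulate(unlist(result$fold_records$selected), nbins = n_feat)
  hist <- tibble::as_tibble(result$features)
  hist$count <- counts
  hist$freq <- counts / nrow(result$fold_records)
  structure(hist, class = c("selection_histogram", class(hist)),
            n_folds = nrow(result$fold_records))
}

#' Candidate nodes from a selection histogram
#'
#' Nodes selected in at least `freq_threshold` of the LOOCV folds. The
#' default of 0.5 asks for selection in a majority of folds; an empty
#' result is a valid outcome, not an error.
#'
#' @param hist A [selection_histogram()].
#' @param freq_threshold Minimum selection frequency (default 0.5).
#' @return Integer vector of feature indices (node indices for a
#'   single-property classifier), possibly empty.
#' @export
select_candidate_nodes <- function(hist, freq_threshold = 0.5) {
  if (!inherits(hist, "selection_histogram"))
    stopf("`hist` must be a selection_histogram")
  if (!is.numeric(freq_threshold) || freq_threshold < 0 || freq_threshold > 1)
    stopf("`freq_threshold` must be in [0, 1]")
  # a zero threshold means "ever selected", not "all nodes"
  which(hist$count > 0L & hist$freq >= freq_threshold)
}

#' Node-wise group tests with FDR control
#'
#' Independent two-sample pooled-variance t-tests (df = N - 2) of C versus
#' NC at each requested node, with Benjamini-Hochberg false-discovery-rate
#' adjustment across the tested nodes at level `q`.
#'
#' @param cohort A [tract_cohort()] with >= 2 subjects per class.
#' @param tract_id,property Profile to test.
#' @param nodes Integer vector of node indices to test (default all).
#' @param q FDR level (default 0.05).
#' @return A tibble with one row per tested node: `node`, `t`, `df`,
#'   `p`, `p_adj`, `significant`.
#' @export
node_group_tests <- function(cohort, tract_id, property, nodes = NULL,
                             q = 0.05) {
  fm <- feature_matrix(cohort, tract_id, property)
  if (is.null(nodes)) nodes <- seq_len(ncol(fm$x))
  nodes <- as.integer(nodes)
  if (any(nodes < 1L | nodes > ncol(fm$x))) stopf("node index out of range")
  gC <- fm$x[fm$y == "C", , drop = FALSE]
  gNC <- fm$x[fm$y == "NC", , drop = FALSE]
  if (nrow(gC) < 2L || nrow(gNC) < 2L) stopf("need >= 2 subjects per class")
  res <- lapply(nodes, function(j) {
    sC <- sd(gC[, j]); sNC <- sd(gNC[, j])
    if (sC == 0 && sNC == 0) stopf("zero variance in both groups at node %d", j)
    two_sample_t(group_summary(nrow(gC), mean(gC[, j]), sC),
                 group_summary(nrow(gNC), mean(gNC[, j]), sNC))
  })
  out <- tibble::tibble(
    tract_id = tract_id, property = property, node = nodes,
    t = vapply(res, `[[`, 1, "t"),
    df = vapply(res, `[[`, 1, "df"),
    p = vapply(res, `[[`, 1, "p"))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  out
}

# split a sorted integer vector into maximal runs of consecutive values
consecutive_runs <- function(nodes) {
  if (length(nodes) == 0L) return(list())
  nodes <- sort(unique(as.integer(nodes)))
  breaks <- c(0L, which(diff(nodes) > 1L), length(nodes))
  lapply(seq_len(length(breaks) - 1L), function(i)
    nodes[(breaks[i] + 1L):breaks[i + 1L]])
}

#' Define predictive tract regions
#'
#' Intersects the frequently selected candidate nodes with the
#' FDR-significant nodes and groups the intersection into maximal runs of
#' consecutive node indices — the "regions" reported per tract and
#' property (e.g. nodes 37-45).
#'
#' @param candidates Integer vector of candidate node indices (from
#'   [select_candidate_nodes()]).
#' @param tests Node-test table from [node_group_tests()], or an integer
#'   vector of significant node indices.
#' @param tract_id,property Identifiers recorded in the output.
#' @return A tibble with one row per region: `tract_id`, `property`,
#'   `region_id`, `start`, `end`, and a `nodes` list-column. Zero rows when
#'   the intersection is empty.
#' @export
define_regions <- function(candidates, tests, tract_id = NULL,
                           property = NULL) {
  if (is.data.frame(tests)) {
    sig <- tests$node[tests$significant]
    tract_id <- tract_id %||% tests$tract_id[1]
    property <- property %||% tests$property[1]
  } else sig <- as.integer(tests)
  runs <- consecutive_runs(intersect(as.integer(candidates), sig))
  tibble::tibble(
    tract_id = rep(tract_id %||% NA_character_, length(runs)),
    property = rep(property %||% NA_character_, length(runs)),
    region_id = seq_along(runs),
    start = vapply(runs, min, 1L),
    end = vapply(runs, max, 1L),
    nodes = runs)
}

# assemble the region-restricted feature matrix across tracts/properties
region_feature_matrix <- function(cohort, regions) {
  if (nrow(regions) == 0L) stopf("empty region set")
  xs <- list(); feats <- list()
  for (i in seq_len(nrow(regions))) {
    tr <- regions$tract_id[i]; pr <- regions$property[i]
    nodes <- regions$nodes[[i]]
    m <- cohort$profiles[[tr]][[pr]]
    if (is.null(m)) stopf("cohort lacks %s/%s", tr, pr)
    xs[[i]] <- m[, nodes, drop = FALSE]
    feats[[i]] <- data.frame(tract_id = tr, property = pr, node = nodes,
                             stringsAsFactors = FALSE)
  }
  x <- do.call(cbind, xs)
  features <- do.call(rbind, feats)
  colnames(x) <- paste(features$tract_id, features$property, features$node,
                       sep = ".")
  list(x = x, y = cohort$subjects$group, features = features)
}

#' Final region-restricted classifier
#'
#' Runs the identical LOOCV pipeline (fold-wise normalization, RFE to
#' `min(10, n_features)`, RBF-SVM) on the features assembled from the
#' selected-and-significant regions across all implicated tracts and
#' properties, and reports its accuracy, AUC and the union of per-fold
#' selected nodes — the package's summary of which specific tract regions
#' carry the predictive signal.
#'
#' @param cohort A [tract_cohort()].
#' @param regions Region table from [define_regions()] (rows from several
#'   tracts/properties may be concatenated with `rbind()`).
#' @param target_k RFE target (default 10, capped at the feature count).
#' @param ... Passed to the LOOCV engine (see [loocv_classify()]).
#' @return An object of class `region_classifier_result`: `accuracy`,
#'   `auc`, `fold_records`, `features`, and `final_selected_nodes` (tibble
#'   of features selected in at least one fold).
#' @export
final_region_classifier <- function(cohort, regions, target_k = 10L, ...) {
  fm <- region_feature_matrix(cohort, regions)
  k <- min(target_k, ncol(fm$x))
  cv <- loocv_matrix(fm$x, fm$y, target_k = k, ...)
  fold_records <- tibble::tibble(
    subject_id = cohort$subjects$subject_id,
    truth = fm$y, predicted = cv$pred, score = cv$score,
    selected = cv$selected)
  sel_union <- sort(unique(unlist(cv$selected)))
  res <- list(regions = regions, fold_records = fold_records,
              features = fm$features, n = nrow(fm$x),
              final_selected_nodes =
                tibble::as_tibble(fm$features[sel_union, , drop = FALSE]))
  res$accuracy <- mean(fold_records$truth == fold_records$predicted)
  res$auc <- auc(fold_records$truth, score = fold_records$score)
  class(res) <- "region_classifier_result"
  res
}

#' @export
print.region_classifier_result <- function(x, ...) {
  cat(sprintf("<region_classifier_result> %d region(s), %d features: accuracy = %.3f, AUC = %.3f\n",
              nrow(x$regions), nrow(x$features), x$accuracy, x$auc))
  sel <- x$final_selected_nodes
  if (nrow(sel)) {
    agg <- stats::aggregate(node ~ tract_id + property, data = sel,
                            FUN = function(v) paste(sort(v), collapse = ","))
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  selected: %s / %s nodes %s\n",
                  agg$tract_id[i], agg$property[i], agg$node[i]))
  }
  invisible(x)
}
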