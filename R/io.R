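# Long-format profile CSV interchange, YAML run configuration.

#' Write and read long-format tract-profile tables
#'
#' The canonical interchange format is a long CSV with one diffusion value
#' per row: columns `subject_id`, `group` (`C`/`NC`), `tract_id`,
#' `property` (`FA`/`MD`/`RD`/`AxD`), `node` (1-based) and `value`.
#' On reading, the grid is validated: duplicate
#' (subject, tract, property, node) rows are an error, unknown tract or
#' property names are an error, and subjects missing any value of an
#' analyzed tract/property are dropped with a warning (mirroring the
#' exclusion of subjects whose image processing failed to yield values for
#' all tracts).
#'
#' @param cohort A [tract_cohort()].
#' @param path CSV file path.
#' @return `read_profiles()` returns a [tract_cohort()];
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(cohort, path) {
  rows <- list()
  for (tr in cohort_tracts(cohort)) {
    for (pr in cohort_properties(cohort, tr)) {
      m <- cohort$profiles[[tr]][[pr]]
      rows[[paste(tr, pr)]] <- tibble::tibble(
        subject_id = rep(rownames(m), each = ncol(m)),
        group = rep(cohort$subjects$group, each = ncol(m)),
        tract_id = tr, property = pr,
        node = rep(seq_len(ncol(m)), times = nrow(m)),
        value = as.vector(t(m)))
    }
  }
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname write_profiles
#' @param n_nodes Expected nodes per profile (default 100).
#' @export
read_profiles <- function(path, n_nodes = 100L) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           group = readr::col_character(),
                           tract_id = readr::col_character(),
                           property = readr::col_character(),
                           node = readr::col_integer(),
                           value = readr::col_double()))
  need <- c("subject_id", "group", "tract_id", "property", "node", "value")
  if (!all(need %in% names(tbl)))
    stopf("profile CSV must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(tbl$tract_id), canonical_tracts())
  if (length(bad)) stopf("unknown tract name(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tbl$property), diffusion_properties())
  if (length(bad)) stopf("unknown property name(s): %s", paste(bad, collapse = ", "))
  if (any(tbl$node < 1L | tbl$node > n_nodes))
    stopf("node indices must be in 1..%d", n_nodes)
  key <- paste(tbl$subject_id, tbl$tract_id, tbl$property, tbl$node)
  if (anyDuplicated(key))
    stopf("duplicate (subject, tract, property, node) rows")
  if (anyNA(tbl$value)) stopf("missing values in profile CSV")

  tracts <- unique(tbl$tract_id)
  props <- unique(tbl$property)
  subj <- unique(tbl[, c("subject_id", "group")])
  if (anyDuplicated(subj$subject_id))
    stopf("conflicting group labels for a subject")

  # completeness: every subject needs the full grid
  expected <- length(tracts) * length(props) * n_nodes
  counts <- table(tbl$subject_id)
  incomplete <- names(counts)[counts < expected]
  if (length(incomplete)) {
    warning(sprintf("dropping %d subject(s) with incomplete profiles: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")),
            call. = FALSE)
    tbl <- tbl[!tbl$subject_id %in% incomplete, , drop = FALSE]
    subj <- subj[!subj$subject_id %in% incomplete, , drop = FALSE]
  }
  if (nrow(subj) == 0L) stopf("no complete subjects in profile CSV")

  ids <- subj$subject_id
  profiles <- list()
  for (tr in tracts) {
    profiles[[tr]] <- list()
    for (pr in props) {
      sub <- tbl[tbl$tract_id == tr & tbl$property == pr, , drop = FALSE]
      m <- matrix(NA_real_, length(ids), n_nodes, dimnames = list(ids, NULL))
      m[cbind(match(sub$subject_id, ids), sub$node)] <- sub$value
      if (anyNA(m)) stopf("incomplete grid for %s/%s", tr, pr)
      profiles[[tr]][[pr]] <- m
    }
  }
  tract_cohort(subjects = subj, profiles = profiles, n_nodes = n_nodes)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end procedure with validation, and
#' round-trips to YAML for provenance. Defaults are the procedure's
#' standard constants: RFE retains 10 nodes, the accuracy screen uses
#' the exact binomial chance threshold at alpha = 0.05, the AUC floor is
#' 0.6, 1000 label permutations, FDR at q = 0.05, selection-frequency
#' threshold 0.5, correlation-group threshold 0.9, SVM cost 1.
#'
#' @param target_k RFE target feature count.
#' @param alpha Significance level of the chance-accuracy screen.
#' @param auc_floor AUC screening floor.
#' @param n_perm Label permutations for the significance test (0 disables
#'   the permutation stage).
#' @param fdr_q FDR level of the node-wise group tests.
#' @param freq_threshold Node selection-frequency threshold.
#' @param corr_threshold Correlation-bias-reduction grouping threshold.
#' @param cost SVM regularization constant.
#' @param use_cbr Use correlation-bias reduction in RFE.
#' @param include_all Also run the concatenated "ALL"-property classifier
#'   per tract.
#' @param seed Integer seed for the permutation stage.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(target_k = 10L, alpha = 0.05, auc_floor = 0.6,
                       n_perm = 1000L, fdr_q = 0.05, freq_threshold = 0.5,
                       corr_threshold = 0.9, cost = 1, use_cbr = TRUE,
                       include_all = TRUE, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, auc_floor >= 0, auc_floor <= 1,
            fdr_q > 0, fdr_q < 1, freq_threshold >= 0, freq_threshold <= 1,
            corr_threshold >= 0, corr_threshold <= 1, cost > 0, n_perm >= 0)
  structure(list(target_k = assert_scalar_count(target_k, "target_k"),
                 alpha = alpha, auc_floor = auc_floor,
                 n_perm = as.integer(n_perm), fdr_q = fdr_q,
                 freq_threshold = freq_threshold,
                 corr_threshold = corr_threshold, cost = cost,
                 use_cbr = isTRUE(use_cbr), include_all = isTRUE(include_all),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
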