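#' Labeled cohort of tract profiles
#'
#' A `tract_cohort` is the unit of analysis: a set of subjects, each
#' labeled converter (`"C"`) or non-converter (`"NC"`), with one
#' `n_nodes`-vector of each diffusion property along each tract. Profiles
#' are stored as per-(tract, property) numeric matrices with one row per
#' subject, which is the layout the classifier consumes directly.
#'
#' @param subjects A data frame with columns `subject_id` (unique character)
#'   and `group` (values `"C"`/`"NC"`).
#' @param profiles Nested list `profiles[[tract]][[property]]`, each a
#'   numeric matrix of dimension `nrow(subjects) x n_nodes` with rownames
#'   equal to `subjects$subject_id`.
#' @param n_nodes Number of nodes per profile (default 100).
#' @param demographics Optional data frame of per-subject covariates
#'   (must contain `subject_id`).
#' @return An object of class `tract_cohort`.
#' @export
tract_cohort <- function(subjects, profiles, n_nodes = 100L,
                         demographics = NULL) {
  subjects <- tibble::as_tibble(subjects)
  if (!all(c("subject_id", "group") %in% names(subjects)))
    stopf("`subjects` needs columns subject_id and group")
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  if (anyDuplicated(subjects$subject_id))
    stopf("duplicate subject_id in cohort")
  if (!all(subjects$group %in% c("C", "NC")))
    stopf("group labels must be 'C' or 'NC'")
  n_nodes <- assert_scalar_count(n_nodes, "n_nodes", 2L)
  for (tr in names(profiles)) {
    for (pr in names(profiles[[tr]])) {
      m <- profiles[[tr]][[pr]]
      if (!is.matrix(m) || nrow(m) != nrow(subjects) || ncol(m) != n_nodes)
        stopf("profile matrix for %s/%s must be %d x %d",
              tr, pr, nrow(subjects), n_nodes)
      if (anyNA(m)) stopf("missing values in %s/%s", tr, pr)
      if (is.null(rownames(m)))
        rownames(profiles[[tr]][[pr]]) <- subjects$subject_id
      else if (!identical(rownames(m), subjects$subject_id))
        profiles[[tr]][[pr]] <- m[subjects$subject_id, , drop = FALSE]
    }
  }
  structure(list(subjects = subjects, profiles = profiles,
                 n_nodes = n_nodes, demographics = demographics),
            class = "tract_cohort")
}

#' @export
print.tract_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<tract_cohort> %d subjects (C: %d, NC: %d)\n",
              nrow(x$subjects), tab[["C"]] %||% 0, tab[["NC"]] %||% 0))
  cat(sprintf("  %d tract(s) x {%s}, %d nodes\n", length(x$profiles),
              paste(unique(unlist(lapply(x$profiles, names))), collapse = ", "),
              x$n_nodes))
  invisible(x)
}

cohort_tracts <- function(cohort) names(cohort$profiles)

cohort_properties <- function(cohort, tract_id = NULL) {
  if (is.null(tract_id)) unique(unlist(lapply(cohort$profiles, names)))
  else names(cohort$profiles[[tract_id]])
}

#' Extract the feature matrix for one tract and property
#'
#' Assembles the subjects-by-nodes matrix the classifier operates on. With
#' `property = "ALL"` the four property profiles of the tract are
#' concatenated column-wise into one wide matrix (nodes tagged
#' `property.node`).
#'
#' @param cohort A [tract_cohort()].
#' @param tract_id Canonical tract name present in the cohort.
#' @param property One of the stored properties, or `"ALL"`.
#' @return List with `x` (numeric matrix), `y` (character group labels) and
#'   `features` (data frame mapping columns to tract/property/node).
#' @export
feature_matrix <- function(cohort, tract_id, property) {
  tract_id <- unname(tract_id)
  property <- unname(property)
  if (!tract_id %in% cohort_tracts(cohort))
    stopf("tract '%s' not present in cohort", tract_id)
  props <- cohort_properties(cohort, tract_id)
  if (identical(property, "ALL")) {
    use <- props
  } else {
    if (!property %in% props)
      stopf("property '%s' not present for tract '%s'", property, tract_id)
    use <- property
  }
  xs <- lapply(use, function(pr) cohort$profiles[[tract_id]][[pr]])
  x <- do.call(cbind, xs)
  features <- do.call(rbind, lapply(use, function(pr)
    data.frame(tract_id = tract_id, property = pr,
               node = seq_len(cohort$n_nodes), stringsAsFactors = FALSE)))
  colnames(x) <- paste(features$property, features$node, sep = ".")
  list(x = x, y = cohort$subjects$group, features = features)
}

# replace the group labels (used by permutation tests)
relabel_cohort <- function(cohort, labels) {
  stopifnot(length(labels) == nrow(cohort$subjects))
  cohort$subjects$group <- as.character(labels)
  cohort
}
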