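# End-to-end procedure: per-tract/property LOOCV screens, chance/AUC screen,
# permutation tests on survivors, selection histograms and FDR node tests,
# region definition, final region-restricted classifier.

#' Benchmark simulation configuration
#'
#' The package's reference ground-truth scenario: three implanted effects
#' in a spatial pattern characteristic of converters — a terminal
#' (hippocampal) MD increase in the right cingulum hippocampal bundle
#' (nodes 90-100), a central AxD increase in the right IFOF (nodes 37-45),
#' and posterior plus anterior AxD increases in the left ILF (nodes 1-10
#' and 80-90) — each with standardized effect size `d`, on a cohort of
#' 34 C / 53 NC subjects.
#'
#' @param d Standardized effect size (default 1.5).
#' @param seed Integer seed.
#' @param n_C,n_NC Group sizes.
#' @return A [sim_config()].
#' @export
benchmark_config <- function(d = 1.5, seed = 1L, n_C = 34L, n_NC = 53L) {
  sim_config(
    n_C = n_C, n_NC = n_NC,
    tracts = c("right_cingulum_hippocampus", "right_ifof", "left_ilf"),
    properties = diffusion_properties(),
    effects = list(
      effect_spec("right_cingulum_hippocampus", "MD", 90:100, d),
      effect_spec("right_ifof", "AxD", 37:45, d),
      effect_spec("left_ilf", "AxD", 1:10, d),
      effect_spec("left_ilf", "AxD", 80:90, d)),
    seed = seed)
}

# effects of a config, as a data frame of implanted (tract, property) pairs
implanted_pairs <- function(config) {
  unique(do.call(rbind, lapply(config$effects, function(ef)
    data.frame(tract_id = ef$tract_id, property = ef$property,
               stringsAsFactors = FALSE))))
}

#' Run the complete classification pipeline
#'
#' Executes, in order: one LOOCV classifier per (tract, property) pair
#' (plus the concatenated `"ALL"` classifier per tract when configured);
#' the predictive-value screen (accuracy above the exact binomial chance
#' threshold AND AUC above the floor); label-permutation significance
#' tests for the survivors; node-selection histograms, candidate nodes and
#' FDR-corrected node-wise group tests for the survivors; region
#' definition; and the final region-restricted classifier. All stage
#' outputs, the configuration and the package version are returned in one
#' report; when `out_dir` is given the report is also written to CSV/JSON
#' files.
#'
#' @param cohort A [tract_cohort()].
#' @param config A [run_config()].
#' @param tracts,properties Subsets to analyze (defaults: everything in
#'   the cohort).
#' @param out_dir Optional output directory for report files.
#' @param verbose Print per-stage progress.
#' @return An object of class `pipeline_report`.
#' @export
run_full_pipeline <- function(cohort, config = run_config(), tracts = NULL,
                              properties = NULL, out_dir = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(cohort, "tract_cohort"), inherits(config, "run_config"))
  tracts <- tracts %||% cohort_tracts(cohort)
  properties <- properties %||% cohort_properties(cohort)
  say <- function(...) if (verbose) message(sprintf(...))

  # stage 1: per-tract/property LOOCV classifiers
  props_run <- c(properties, if (config$include_all && length(properties) > 1L) "ALL")
  results <- list()
  for (tr in tracts) for (pr in props_run) {
    say("LOOCV %s / %s", tr, pr)
    results[[paste(tr, pr, sep = "|")]] <-
      loocv_classify(cohort, tr, pr, cost = config$cost,
                     target_k = config$target_k,
                     corr_threshold = config$corr_threshold,
                     use_cbr = config$use_cbr)
  }

  # stage 2: chance/AUC screen
  n <- nrow(cohort$subjects)
  acc_threshold <- chance_threshold(n, config$alpha)
  screen <- screen_predictive(results, acc_threshold = acc_threshold,
                              auc_floor = config$auc_floor)
  survivors <- which(screen$predictive)
  say("screen: %d of %d predictive (acc > %.2f, AUC > %.2f)",
      length(survivors), nrow(screen), acc_threshold, config$auc_floor)

  # stage 3: permutation tests on survivors
  permutations <- list()
  if (config$n_perm > 0L) {
    for (i in survivors) {
      key <- paste(screen$tract_id[i], screen$property[i], sep = "|")
      say("permutation test %s (%d perms)", key, config$n_perm)
      permutations[[key]] <- permutation_test(
        cohort, screen$tract_id[i], screen$property[i],
        n_perm = config$n_perm, seed = config$seed + i,
        observed = results[[key]], cost = config$cost,
        target_k = config$target_k, corr_threshold = config$corr_threshold,
        use_cbr = config$use_cbr)
    }
  }

  # stage 4: histograms, candidate nodes, FDR node tests, regions
  histograms <- list(); node_tests <- list(); region_rows <- list()
  for (i in survivors) {
    tr <- screen$tract_id[i]; pr <- screen$property[i]
    if (pr == "ALL") next # regions are defined on single properties
    key <- paste(tr, pr, sep = "|")
    hist <- selection_histogram(results[[key]])
    histograms[[key]] <- hist
    cand <- select_candidate_nodes(hist, config$freq_threshold)
    if (length(cand) == 0L) next
    tests <- node_group_tests(cohort, tr, pr, nodes = cand, q = config$fdr_q)
    node_tests[[key]] <- tests
    reg <- define_regions(cand, tests)
    if (nrow(reg)) region_rows[[key]] <- reg
  }
  regions <- if (length(region_rows)) dplyr::bind_rows(region_rows)
             else tibble::tibble()

  # stage 5: final region-restricted classifier
  final <- NULL
  if (nrow(regions) > 0L) {
    say("final region classifier on %d region(s)", nrow(regions))
    final <- final_region_classifier(
      cohort, regions, target_k = config$target_k, cost = config$cost,
      corr_threshold = config$corr_threshold, use_cbr = config$use_cbr)
  }

  report <- structure(list(
    config = config, version = as.character(packageVersion("tractclass")),
    acc_threshold = acc_threshold, results = results, screen = screen,
    permutations = permutations, histograms = histograms,
    node_tests = node_tests, regions = regions, final = final),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d classifier(s), %d predictive, %d region(s)\n",
              nrow(x$screen), sum(x$screen$predictive), nrow(x$regions)))
  if (!is.null(x$final))
    cat(sprintf("  final region classifier: accuracy = %.3f, AUC = %.3f\n",
                x$final$accuracy, x$final$auc))
  invisible(x)
}

# wide tract x property table of one metric
metric_table <- function(screen, metric) {
  tidyr::pivot_wider(screen[, c("tract_id", "property", metric)],
                     names_from = "property",
                     values_from = tidyr::all_of(metric))
}

#' Write a pipeline report to files
#'
#' Accuracy and AUC tables (tract x property CSV), the screen table,
#' selection histograms (node, frequency, significance flag), permutation
#' null distributions (JSON), the region table, and a JSON summary
#' embedding the run configuration and package version.
#'
#' @param report A `pipeline_report` from [run_full_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(metric_table(report$screen, "accuracy"),
                   file.path(out_dir, "accuracy_table.csv"))
  readr::write_csv(metric_table(report$screen, "auc"),
                   file.path(out_dir, "auc_table.csv"))
  readr::write_csv(report$screen, file.path(out_dir, "screen.csv"))
  if (length(report$histograms)) {
    hs <- dplyr::bind_rows(lapply(report$histograms, function(h) {
      key <- paste(h$tract_id[1], h$property[1], sep = "|")
      tests <- report$node_tests[[key]]
      h$significant <- if (!is.null(tests))
        h$node %in% tests$node[tests$significant] else FALSE
      h
    }))
    readr::write_csv(hs, file.path(out_dir, "selection_histograms.csv"))
  }
  if (length(report$permutations)) {
    jsonlite::write_json(
      lapply(report$permutations, function(p)
        list(tract_id = p$tract_id, property = p$property,
             observed_accuracy = p$observed_accuracy,
             empirical_p = p$empirical_p, t_test_p = p$t_test_p,
             null_accuracies = p$null_accuracies)),
      file.path(out_dir, "permutations.json"), auto_unbox = TRUE, digits = NA)
  }
  if (nrow(report$regions)) {
    flat <- report$regions
    flat$nodes <- vapply(flat$nodes, paste, "", collapse = ",")
    readr::write_csv(flat, file.path(out_dir, "regions.csv"))
  }
  summary <- list(
    package_version = report$version,
    config = unclass(report$config),
    acc_threshold = report$acc_threshold,
    n_predictive = sum(report$screen$predictive),
    final = if (!is.null(report$final))
      list(accuracy = report$final$accuracy, auc = report$final$auc,
           selected = report$final$final_selected_nodes))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
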