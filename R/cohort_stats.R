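# Cohort comparison statistics computed from printed group summaries or raw
# demographics (the demographic table's t-tests and chi-square tests).

#' Group summary statistics
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' group_summary(34, 76.3, 7.7) # converter-group age
group_summary <- function(n, mean, sd) {
  n <- assert_scalar_count(n, "n", 2L)
  if (!is.numeric(mean) || length(mean) != 1L) stopf("`mean` must be a number")
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0)
    stopf("`sd` must be a non-negative number")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Two-sample t-test from group summaries
#'
#' Pooled-variance (equal variances assumed) two-sample t with
#' `df = n1 + n2 - 2` and a two-sided p-value, matching the df = 85
#' convention of an 87-subject two-group comparison. Welch's unequal-
#' variance form is available via `var_equal = FALSE`.
#'
#' @param g1,g2 [group_summary()] objects (difference is `g1 - g2`).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' two_sample_t(group_summary(34, 76.3, 7.7), group_summary(53, 74.3, 8.1))
two_sample_t <- function(g1, g2, var_equal = TRUE) {
  if (!inherits(g1, "group_summary") || !inherits(g2, "group_summary"))
    stopf("`g1` and `g2` must be group_summary objects")
  if (g1$sd == 0 && g2$sd == 0) stopf("both group SDs are zero")
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  t <- (g1$mean - g2$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square `sum((O - E)^2 / E)` with 1 degree of freedom; the
#' Yates continuity correction is off by default (the convention matching
#' the cohort table's printed statistics).
#'
#' @param table 2x2 numeric matrix of counts (group x binary trait), or
#'   the count `a` when the four cells are given separately.
#' @param b,c,d Remaining cells `rbind(c(a, b), c(c, d))` when `table` is
#'   scalar.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' # cardiovascular history: C 11/23, NC 14/39
#' chi_square_2x2(rbind(c(11, 23), c(14, 39)))
chi_square_2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                           correct = FALSE) {
  if (length(table) == 1L) table <- rbind(c(table, b), c(c, d))
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || anyNA(table) || any(table < 0))
    stopf("`table` must be a 2x2 matrix of non-negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("chi-square undefined: zero row or column margin")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Demographic comparison table for a cohort
#'
#' Convenience wrapper reproducing the usual cohort-comparison layout:
#' pooled t-tests for continuous covariates and an uncorrected chi-square
#' for sex, computed from the cohort's demographics.
#'
#' @param cohort A [tract_cohort()] with demographics attached (see
#'   [generate_demographics()]).
#' @return A tibble with one row per covariate: group summaries and the
#'   test statistic and p-value.
#' @export
demographics_table <- function(cohort) {
  dem <- cohort$demographics
  if (is.null(dem)) stopf("cohort has no demographics")
  dem <- merge(dem, cohort$subjects, by = "subject_id")
  rows <- list()
  for (v in intersect(c("age", "mmse"), names(dem))) {
    gC <- dem[[v]][dem$group == "C"]; gNC <- dem[[v]][dem$group == "NC"]
    tt <- two_sample_t(group_summary(length(gC), mean(gC), sd(gC)),
                       group_summary(length(gNC), mean(gNC), sd(gNC)))
    rows[[v]] <- tibble::tibble(
      variable = v, C = sprintf("%.1f (%.1f)", mean(gC), sd(gC)),
      NC = sprintf("%.1f (%.1f)", mean(gNC), sd(gNC)),
      statistic = tt$t, df = tt$df, p = tt$p)
  }
  if ("sex" %in% names(dem)) {
    tab <- table(factor(dem$group, c("C", "NC")),
                 factor(dem$sex, c("F", "M")))
    cs <- chi_square_2x2(unclass(tab))
    rows$sex <- tibble::tibble(
      variable = "sex (F/M)",
      C = sprintf("%d/%d", tab["C", "F"], tab["C", "M"]),
      NC = sprintf("%d/%d", tab["NC", "F"], tab["NC", "M"]),
      statistic = cs$statistic, df = cs$df, p = cs$p)
  }
  do.call(rbind, rows)
}
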