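#' 2x2 contingency table
#'
#' Counts with rows = groups and columns = outcome yes/no. Stored as an
#' integer matrix of class `contingency_2x2`.
#'
#' @param a,b,c,d non-negative integer counts: `a` = group1/yes, `b` =
#'   group1/no, `c` = group2/yes, `d` = group2/no.
#' @param labels optional character(2) row labels.
#' @return `contingency_2x2` matrix.
#' @export
contingency_2x2 <- function(a, b, c, d, labels = c("group1", "group2")) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("contingency counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    stop_input("contingency table is empty (total = 0)")
  }
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(labels, c("yes", "no")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Tabulate herb usage against a diagnosis
#'
#' Builds the usage-by-diagnosis 2x2 table: rows are diagnosis = label /
#' other, columns are used / unused.
#'
#' @param cohort a cohort data.frame (see [cohort-schema]).
#' @param disease_label diagnosis string defining the case group.
#' @return `contingency_2x2` with cells (case&used, case&unused,
#'   other&used, other&unused).
#' @export
build_usage_table <- function(cohort, disease_label) {
  if (nrow(cohort) == 0L) {
    stop_input("cohort is empty")
  }
  case <- cohort$diagnosis == disease_label
  used <- cohort$used_herb
  contingency_2x2(sum(case & used), sum(case & !used),
                  sum(!case & used), sum(!case & !used),
                  labels = c(disease_label, "other"))
}

#' Pearson chi-square test on a 2x2 table
#'
#' The statistic sums the squared standardized deviations of observed from
#' independence-expected counts over the four cells; the p-value comes
#' from the chi-square distribution with 1 df. The continuity correction is
#' off by default.
#'
#' @param table a `contingency_2x2` (or any 2x2 count matrix).
#' @param yates apply the Yates continuity correction.
#' @return list with `statistic`, `df` (always 1) and `p`.
#' @examples
#' chi_square_test(contingency_2x2(76, 48, 92, 102))$p
#' @export
chi_square_test <- function(table, yates = FALSE) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_input("degenerate table: a row or column total is zero")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  if (any(res$expected <= 0)) {
    stop_input("chi-square requires positive expected counts")
  }
  list(statistic = unname(res$statistic), df = 1L,
       p = unname(res$p.value))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test for comparing group means (ages, lengths of
#' stay). Two-sided.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df` and `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_input("each group needs at least 2 values")
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    # degenerate: no sampling variability at all
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0))
  }
  res <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Symptom improvement ratio
#'
#' Percentage of patients presenting a symptom at admission whose symptom
#' is relieved at discharge, as an exact rational rounded half-up to two
#' decimals. Undefined (`NA`) when nobody presents the symptom.
#'
#' @param relieved,present non-negative integers, `relieved <= present`.
#'   Vectorized.
#' @return percent in \[0, 100\], or `NA` where `present == 0`.
#' @examples
#' improvement_ratio(19, 32)  # 59.38
#' @export
improvement_ratio <- function(relieved, present) {
  if (any(relieved < 0) || any(present < 0)) {
    stop_input("counts must be non-negative")
  }
  if (any(relieved > present)) {
    stop_input("relieved count exceeds present count")
  }
  out <- rep(NA_real_, length(present))
  ok <- present > 0
  out[ok] <- round_half_up(100 * relieved[ok] / present[ok], 2L)
  out
}

symptom_presence_counts <- function(symptom_list, symptoms) {
  if (length(symptom_list) == 0L) {
    return(stats::setNames(integer(length(symptoms)), symptoms))
  }
  tab <- table(factor(unlist(symptom_list), levels = symptoms))
  stats::setNames(as.integer(tab), symptoms)
}

#' Symptom improvement table by usage group
#'
#' For each symptom, counts patients presenting it at admission and
#' patients with it relieved, stratified by herb usage, with improvement
#' ratios per group. Rows are sorted by used-group relieved count
#' descending, ties broken alphabetically.
#'
#' @param cohort a cohort data.frame.
#' @param symptoms character vector of symptom terms to report.
#' @return data.frame with columns `symptom`, `used_relieved`,
#'   `used_present`, `unused_relieved`, `unused_present`, `used_ratio`,
#'   `unused_ratio`.
#' @export
build_improvement_table <- function(cohort, symptoms) {
  if (length(symptoms) == 0L) {
    stop_input("symptoms must be non-empty")
  }
  symptoms <- unique(normalize_terms(symptoms))
  used <- cohort$used_herb
  up <- symptom_presence_counts(cohort$admission_symptoms[used], symptoms)
  ur <- symptom_presence_counts(cohort$relieved_symptoms[used], symptoms)
  np <- symptom_presence_counts(cohort$admission_symptoms[!used], symptoms)
  nr <- symptom_presence_counts(cohort$relieved_symptoms[!used], symptoms)
  out <- data.frame(symptom = symptoms,
                    used_relieved = ur, used_present = up,
                    unused_relieved = nr, unused_present = np,
                    used_ratio = improvement_ratio(ur, up),
                    unused_ratio = improvement_ratio(nr, np),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$used_relieved, out$symptom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most frequent admission symptoms
#'
#' Ranks symptoms by admission prevalence within a usage group and returns
#' the top `k`. Ties are broken alphabetically. With `relieved_only =
#' TRUE`, candidates are restricted to symptoms recorded as relieved for at
#' least one patient in the whole cohort — the relevant universe when the
#' selection feeds a relief-mechanism analysis.
#'
#' @param cohort a cohort data.frame.
#' @param group `"used"`, `"unused"` or `"all"`.
#' @param k number of symptoms to return (>= 1).
#' @param relieved_only restrict candidates to relief-tracked symptoms.
#' @return data.frame with columns `symptom`, `count`, at most `k` rows.
#' @export
rank_admission_symptoms <- function(cohort, group = c("used", "unused", "all"),
                                    k = 5L, relieved_only = FALSE) {
  group <- match.arg(group)
  if (k < 1L) stop_input("k must be >= 1")
  sel <- switch(group,
                used = cohort$used_herb,
                unused = !cohort$used_herb,
                all = rep(TRUE, nrow(cohort)))
  if (!any(sel)) stop_input("group '", group, "' is empty")
  adm <- cohort$admission_symptoms[sel]
  universe <- sort(unique(unlist(adm)))
  if (relieved_only) {
    relieved_any <- unique(unlist(cohort$relieved_symptoms))
    universe <- intersect(universe, relieved_any)
  }
  if (length(universe) == 0L) {
    return(data.frame(symptom = character(0), count = integer(0)))
  }
  counts <- symptom_presence_counts(adm, universe)
  ord <- order(-counts, universe)
  top <- utils::head(ord, k)
  data.frame(symptom = universe[top], count = unname(counts[top]),
             stringsAsFactors = FALSE)
}
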