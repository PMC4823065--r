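#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact test of association for the table `[[a, b], [c, d]]` using the
#' minimum-likelihood two-sided convention: with the margins fixed, the
#' p-value sums the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance guarding floating-point ties).  Probabilities are computed with
#' log-factorial arithmetic, so large counts do not overflow.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1: `a`, `b`;
#'   row 2: `c`, `d`), e.g. mutated/unmutated patients in relapsed vs
#'   non-relapsed groups.
#' @param rel_tol Relative tolerance for comparing table probabilities
#'   (default 1e-7).
#' @param midp If `TRUE`, return the mid-p variant (half weight on tables
#'   exactly as probable as the observed one).
#' @return The two-sided p-value in (0, 1].  Any zero margin means no
#'   association is testable: returns 1 with a warning.
#' @examples
#' fisher_exact_two_sided(13, 15, 5, 25) # 0.0225
#' @export
fisher_exact_two_sided <- function(a, b, c, d, rel_tol = 1e-7, midp = FALSE) {
  check_count(c(a, b, c, d), "cell counts")
  m <- a + b # row 1 total
  n <- c + d # row 2 total
  k <- a + c # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warn("a zero margin admits only one table; p = 1")
    return(1)
  }
  # log P(x in cell a | margins) via log-factorials
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  support <- max(0, k - n):min(k, m)
  logp <- lp(support)
  logp_obs <- lp(a)
  thresh <- logp_obs + log1p(rel_tol)
  if (midp) {
    tied <- abs(logp - logp_obs) <= abs(log1p(rel_tol))
    p <- sum(exp(logp[logp <= thresh & !tied])) + 0.5 * sum(exp(logp[tied]))
  } else {
    p <- sum(exp(logp[logp <= thresh]))
  }
  min(p, 1)
}

unique_patients <- function(table, group, genes = NULL, cohort = NULL) {
  rows <- table$group == group
  if (!is.null(genes)) rows <- rows & table$gene %in% genes
  if (!is.null(cohort)) rows <- rows & table$cohort %in% cohort
  unique(table$patient[rows])
}

#' Fraction of patients in a group carrying any somatic mutation
#'
#' A patient with several mutations — in one gene or several — is counted
#' once.  The denominator is the number of patients sequenced in the group,
#' supplied explicitly or read from the table's `group_sizes` metadata
#' (patients without mutations have no table rows, so it can never be
#' inferred from the records).
#'
#' @param table A [as_cohort_mutation_table()].
#' @param group `"relapsed"` or `"non_relapsed"`.
#' @param group_size Number of patients sequenced in the group; defaults to
#'   the table's `group_sizes` attribute.
#' @param cohort Optional cohort filter (e.g. `"extension"`).
#' @return Percentage, rounded to 1 decimal.
#' @export
mutated_patient_fraction <- function(table, group, group_size = NULL,
                                     cohort = NULL) {
  if (is.null(group_size)) {
    group_size <- attr(table, "group_sizes")[[group]]
  }
  if (is.null(group_size) || is.na(group_size)) {
    abort("group size not supplied and absent from table metadata",
      class = "relapsekit_value_error")
  }
  n <- length(unique_patients(table, group, cohort = cohort))
  round_half_up(100 * n / group_size, 1)
}

#' Per-gene recurrence frequency among relapsed patients
#'
#' @param table A [as_cohort_mutation_table()].
#' @param gene Gene symbol.
#' @param denominator Number of relapsed patients the frequency refers to.
#' @return Percentage of relapsed patients with at least one mutation in
#'   `gene`, rounded to 1 decimal.
#' @export
gene_frequency <- function(table, gene, denominator) {
  stopifnot(denominator > 0)
  n <- length(unique_patients(table, "relapsed", genes = gene))
  round_half_up(100 * n / denominator, 1)
}

#' Relapse-associated genes
#'
#' A gene is relapse-associated when (i) at least one relapsed patient's
#' mutation in it is retained from diagnosis to relapse (`shared`) or
#' selectively acquired at relapse (`relapse_specific`), (ii) it is mutated
#' in at least two relapsed cases, and (iii) it is mutated in no non-relapsed
#' case.
#'
#' @param table A [as_cohort_mutation_table()].
#' @return Sorted character vector of qualifying gene symbols.
#' @export
relapse_associated_genes <- function(table) {
  genes <- unique(table$gene)
  keep <- vapply(genes, function(g) {
    rel <- length(unique_patients(table, "relapsed", genes = g))
    nonrel <- length(unique_patients(table, "non_relapsed", genes = g))
    persists <- any(table$gene == g & table$group == "relapsed" &
      table$status %in% c("shared", "relapse_specific"))
    rel >= 2 && nonrel == 0 && persists
  }, logical(1))
  sort(genes[keep])
}

#' Fraction of patients mutated in a gene set
#'
#' Used for enrichment summaries such as the epigenetic-regulator gene set
#' (SETD2, CREBBP, KDM6A, and the epigenetically acting transcription
#' factors NR3C1 and PAX5).
#'
#' @param table A [as_cohort_mutation_table()].
#' @param gene_set Character vector of gene symbols.
#' @param group_size Denominator: number of patients the fraction refers to.
#' @param group Patient group to count in (default `"relapsed"`).
#' @param cohort Optional cohort filter.
#' @return Percentage, rounded to 1 decimal.
#' @export
epigenetic_regulator_fraction <- function(table, gene_set, group_size,
                                          group = "relapsed", cohort = NULL) {
  stopifnot(group_size > 0)
  if (length(gene_set) == 0) {
    return(0)
  }
  n <- length(unique_patients(table, group, genes = gene_set, cohort = cohort))
  round_half_up(100 * n / group_size, 1)
}
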