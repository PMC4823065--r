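#' Blast-adjusted variant-in-tumor percentage
#'
#' Converts raw read counts to the percentage of tumor cells estimated to
#' carry the variant, by dividing the variant allele frequency by the blast
#' fraction of the sample: `100 * (var / (var + wt)) / (blast_pct / 100)`.
#' Remission (CR) samples have no blast estimate; passing `blast_pct = NA`
#' returns the raw VAF percentage unadjusted.  Results are rounded half away
#' from zero to one decimal, the precision of the published table; values
#' above 100 (variant apparently in more cells than the blast count allows,
#' e.g. loss of heterozygosity or an underestimated blast fraction) are
#' returned as computed and flagged in the `"super_clonal"` attribute.
#'
#' @param var_reads,wt_reads Non-negative integer vectors of variant and
#'   wild-type read counts; their sum must be positive.
#' @param blast_pct Blast percentage in (0, 100], or `NA` for unadjusted
#'   remission rows.  Recycled against the read counts.
#' @return Numeric vector of percentages (1 decimal) with a logical
#'   `"super_clonal"` attribute of the same length.
#' @examples
#' adjusted_vaf(23, 18, 90)  # 62.3
#' adjusted_vaf(6, 166, NA)  # 3.5 (raw VAF, remission sample)
#' @export
adjusted_vaf <- function(var_reads, wt_reads, blast_pct = NA_real_) {
  n <- max(length(var_reads), length(wt_reads), length(blast_pct))
  var_reads <- rep_len(var_reads, n)
  wt_reads <- rep_len(wt_reads, n)
  blast_pct <- rep_len(blast_pct, n)
  check_count(var_reads, "var_reads")
  check_count(wt_reads, "wt_reads")
  total <- var_reads + wt_reads
  if (any(total == 0)) {
    abort("var_reads + wt_reads must be > 0", class = "relapsekit_value_error")
  }
  if (any(!is.na(blast_pct) & (blast_pct <= 0 | blast_pct > 100))) {
    abort("blast_pct must lie in (0, 100] (or NA for remission rows)",
      class = "relapsekit_value_error")
  }
  raw <- 100 * var_reads / total
  out <- ifelse(is.na(blast_pct), raw, raw / (blast_pct / 100))
  out <- round_half_up(out, 1)
  attr(out, "super_clonal") <- out > 100
  out
}

#' Mutation distribution status across diagnosis and relapse
#'
#' @param present_at_diagnosis,present_at_relapse Logical vectors (recycled).
#' @return Character vector: `"shared"`, `"diagnosis_specific"` or
#'   `"relapse_specific"`.  A mutation absent at both stages is an error —
#'   it is not a mutation of this patient.
#' @export
mutation_status <- function(present_at_diagnosis, present_at_relapse) {
  n <- max(length(present_at_diagnosis), length(present_at_relapse))
  d <- rep_len(as.logical(present_at_diagnosis), n)
  r <- rep_len(as.logical(present_at_relapse), n)
  if (any(!d & !r)) {
    abort("mutation absent at both diagnosis and relapse",
      class = "relapsekit_value_error")
  }
  dplyr::case_when(d & r ~ "shared", d ~ "diagnosis_specific",
    TRUE ~ "relapse_specific")
}

#' Classify the clonal evolution pattern of a relapse
#'
#' Patient-level classification from the per-mutation distribution statuses,
#' using mutation sharing alone:
#'
#' * no shared mutations — the relapse carries a completely distinct mutation
#'   set: `"second_malignancy"`;
#' * shared mutations only — the relapse clone pre-existed as a subclone of
#'   the diagnosed tumor: `"subclone_survival"`;
#' * shared plus stage-specific mutations — diagnosis and relapse clones
#'   diverged from a common progenitor: `"common_progenitor"`.
#'
#' @param statuses Non-empty character vector of statuses as returned by
#'   [mutation_status()].
#' @return One of `"subclone_survival"`, `"common_progenitor"`,
#'   `"second_malignancy"`.
#' @export
classify_pattern <- function(statuses) {
  if (length(statuses) == 0) {
    abort("at least one mutation status required",
      class = "relapsekit_value_error")
  }
  bad <- setdiff(unique(statuses),
    c("diagnosis_specific", "shared", "relapse_specific"))
  if (length(bad) > 0) {
    abort(paste0("unknown status: ", paste(bad, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  s <- sum(statuses == "shared")
  d <- sum(statuses == "diagnosis_specific")
  r <- sum(statuses == "relapse_specific")
  if (s == 0) {
    "second_malignancy"
  } else if (d == 0 && r == 0) {
    "subclone_survival"
  } else {
    "common_progenitor"
  }
}

#' Direction of the adjusted-VAF shift from diagnosis to relapse
#'
#' @param diag_adj,relapse_adj Adjusted variant-in-tumor percentages
#'   ([adjusted_vaf()]) at diagnosis and relapse.
#' @param min_shift Minimum change in percentage points to call a direction
#'   (default 5; smaller changes are `"stable"`).
#' @return Character vector: `"rising"`, `"stable"` or `"falling"`.
#' @export
vaf_shift <- function(diag_adj, relapse_adj, min_shift = 5) {
  stopifnot(all(diag_adj >= 0), all(relapse_adj >= 0), min_shift >= 0)
  delta <- relapse_adj - diag_adj
  dplyr::case_when(delta > min_shift ~ "rising", delta < -min_shift ~ "falling",
    TRUE ~ "stable")
}

#' Per-mutation presence calls from a read-count table
#'
#' Declares a mutation present at a stage when it has at least `min_reads`
#' variant reads and a raw VAF of at least `min_vaf` — a detection rule for
#' deep targeted counts, not a somatic filter (see
#' [call_somatic_candidates()] for candidate selection).
#'
#' @param readcounts Read-count table as returned by
#'   [read_readcount_table()] or [simulate_patient()]: one row per
#'   (patient, gene, aa_change, stage).
#' @param min_reads Minimum variant reads to call presence (default 3).
#' @param min_vaf Minimum raw VAF to call presence (default 0.02).
#' @return Tibble with one row per (patient, gene, aa_change):
#'   `present_at_diagnosis`, `present_at_relapse`, `status`.
#' @export
mutation_statuses_from_readcounts <- function(readcounts, min_reads = 3,
                                              min_vaf = 0.02) {
  rc <- readcounts
  rc$.present <- rc$var_reads >= min_reads &
    vaf_of(rc$var_reads, rc$wt_reads) >= min_vaf
  wide <- rc |>
    dplyr::group_by(.data$patient, .data$gene, .data$aa_change) |>
    dplyr::summarise(
      present_at_diagnosis = any(.data$.present[.data$stage == "diagnosis"]),
      present_at_relapse = any(.data$.present[.data$stage == "relapse"]),
      .groups = "drop"
    )
  wide <- wide[wide$present_at_diagnosis | wide$present_at_relapse, ]
  wide$status <- mutation_status(wide$present_at_diagnosis,
    wide$present_at_relapse)
  wide
}

#' Full clonal evolution report for one or more patients
#'
#' Computes, per mutation, the blast-adjusted variant-in-tumor percentages at
#' diagnosis and relapse, the raw remission VAF, the distribution status and
#' the VAF shift; and, per patient, the clonal evolution pattern.
#'
#' @inheritParams mutation_statuses_from_readcounts
#' @param min_shift Passed to [vaf_shift()].
#' @return A list with `mutations` (per-mutation tibble) and `patterns`
#'   (per-patient tibble with a `pattern` column).
#' @export
clonal_report <- function(readcounts, min_reads = 3, min_vaf = 0.02,
                          min_shift = 5) {
  adj <- function(v, w, b) {
    if (is.na(v) || v + w <= 0) NA_real_ else as.numeric(adjusted_vaf(v, w, b))
  }
  wide <- readcounts |>
    dplyr::group_by(.data$patient, .data$gene, .data$aa_change) |>
    dplyr::summarise(
      diagnosis_pct = {
        i <- which(.data$stage == "diagnosis")[1]
        if (is.na(i)) NA_real_ else
          adj(.data$var_reads[i], .data$wt_reads[i], .data$blast_pct[i])
      },
      relapse_pct = {
        i <- which(.data$stage == "relapse")[1]
        if (is.na(i)) NA_real_ else
          adj(.data$var_reads[i], .data$wt_reads[i], .data$blast_pct[i])
      },
      remission_pct = {
        i <- which(.data$stage == "CR")[1]
        if (is.na(i)) NA_real_ else
          adj(.data$var_reads[i], .data$wt_reads[i], NA_real_)
      },
      .groups = "drop"
    )
  statuses <- mutation_statuses_from_readcounts(readcounts, min_reads, min_vaf)
  mutations <- dplyr::inner_join(wide, statuses,
    by = c("patient", "gene", "aa_change"))
  mutations$shift <- vaf_shift(
    ifelse(is.na(mutations$diagnosis_pct), 0, mutations$diagnosis_pct),
    ifelse(is.na(mutations$relapse_pct), 0, mutations$relapse_pct),
    min_shift
  )
  patterns <- mutations |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(
      n_shared = sum(.data$status == "shared"),
      n_diagnosis_specific = sum(.data$status == "diagnosis_specific"),
      n_relapse_specific = sum(.data$status == "relapse_specific"),
      pattern = classify_pattern(.data$status),
      .groups = "drop"
    )
  list(mutations = mutations, patterns = patterns)
}
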