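#' Construct a variant call table
#'
#' One row per variant observation in one sample.  Coordinates are 1-based
#' (VCF convention).  `effect` must be one of the recognised classes; see
#' [effect_levels()].
#'
#' @param df Data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `effect`, `var_reads`, `ref_reads`, `mapping_quality`,
#'   `base_quality`.
#' @return A tibble of class `variant_calls`.
#' @export
as_variant_calls <- function(df) {
  req <- c(
    "sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
    "var_reads", "ref_reads", "mapping_quality", "base_quality"
  )
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "relapsekit_schema_error")
  }
  df <- as_tibble(df)[req]
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1L)) {
    abort("`pos` must be >= 1 (1-based coordinates)",
      class = "relapsekit_value_error")
  }
  check_count(df$var_reads, "var_reads")
  check_count(df$ref_reads, "ref_reads")
  bad_eff <- setdiff(unique(df$effect), EFFECT_LEVELS)
  if (length(bad_eff) > 0) {
    abort(paste0("unknown effect class: ", paste(bad_eff, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  df$var_reads <- as.integer(df$var_reads)
  df$ref_reads <- as.integer(df$ref_reads)
  class(df) <- c("variant_calls", class(df))
  df
}

#' Recognised variant effect classes
#'
#' @return Character vector of the effect classes accepted in variant calls.
#' @export
effect_levels <- function() EFFECT_LEVELS

#' Filtering thresholds for candidate somatic mutation selection
#'
#' Defaults are the published selection rule: variant allele frequency
#' >= 15% with >= 20x coverage in either tumor sample, < 0.5% in the
#' remission sample, and the upstream call-quality rule (mapping quality
#' > 30, base quality > 15, variant reads > 3; all strict inequalities).
#'
#' @param min_tumor_vaf Minimum tumor VAF (fraction), inclusive. Default 0.15.
#' @param min_tumor_depth Minimum tumor depth at the site, inclusive. Default 20.
#' @param max_remission_vaf Maximum remission VAF (fraction), exclusive. Default 0.005.
#' @param min_mapping_quality Calls must exceed this mapping quality. Default 30.
#' @param min_base_quality Calls must exceed this base quality. Default 15.
#' @param min_var_reads Calls must have strictly more variant reads than this. Default 3.
#' @param tumor_rule `"either"` (default) requires the VAF + depth condition in
#'   at least one of diagnosis/relapse; `"both"` requires it in both.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_tumor_vaf = 0.15,
                              min_tumor_depth = 20L,
                              max_remission_vaf = 0.005,
                              min_mapping_quality = 30,
                              min_base_quality = 15,
                              min_var_reads = 3L,
                              tumor_rule = c("either", "both")) {
  tumor_rule <- match.arg(tumor_rule)
  check_fraction(min_tumor_vaf, "min_tumor_vaf")
  check_fraction(max_remission_vaf, "max_remission_vaf")
  stopifnot(
    min_tumor_depth >= 0, min_mapping_quality >= 0,
    min_base_quality >= 0, min_var_reads >= 0
  )
  structure(
    list(
      min_tumor_vaf = min_tumor_vaf,
      min_tumor_depth = as.integer(min_tumor_depth),
      max_remission_vaf = max_remission_vaf,
      min_mapping_quality = min_mapping_quality,
      min_base_quality = min_base_quality,
      min_var_reads = as.integer(min_var_reads),
      tumor_rule = tumor_rule
    ),
    class = "filter_thresholds"
  )
}

#' Construct a matched patient trio
#'
#' Bundles the matched diagnosis, complete remission (CR) and relapse call
#' sets of one patient together with the stem cell donor's call set.  The CR
#' sample is the germline reference; relapse calls are present iff the
#' patient relapsed.
#'
#' @param patient Patient identifier.
#' @param diagnosis,cr,donor Variant call tables ([as_variant_calls()]).
#' @param relapse Variant call table, or `NULL` for non-relapsed patients.
#' @param group `"relapsed"` or `"non_relapsed"`.
#' @return A list of class `patient_trio`.
#' @export
patient_trio <- function(patient, diagnosis, cr, relapse = NULL, donor,
                         group = c("relapsed", "non_relapsed")) {
  group <- match.arg(group)
  if (group == "relapsed" && is.null(relapse)) {
    abort("relapsed patients must carry a relapse call set",
      class = "relapsekit_value_error")
  }
  if (group == "non_relapsed" && !is.null(relapse)) {
    abort("non-relapsed patients cannot carry a relapse call set",
      class = "relapsekit_value_error")
  }
  structure(
    list(
      patient = patient,
      diagnosis = as_variant_calls(diagnosis),
      cr = as_variant_calls(cr),
      relapse = if (!is.null(relapse)) as_variant_calls(relapse),
      donor = as_variant_calls(donor),
      group = group
    ),
    class = "patient_trio"
  )
}

#' Construct an STR peak-height profile
#'
#' Long table of electropherogram peaks for one sample: one row per
#' (locus, allele) with the allele identified by its repeat number and
#' quantified by peak height.
#'
#' @param df Data frame with columns `sample_id`, `locus`, `allele_repeats`,
#'   `height`.
#' @return A tibble of class `str_profile`.
#' @export
as_str_profile <- function(df) {
  req <- c("sample_id", "locus", "allele_repeats", "height")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "relapsekit_schema_error")
  }
  df <- as_tibble(df)[req]
  if (any(df$height <= 0)) {
    abort("peak heights must be > 0", class = "relapsekit_value_error")
  }
  check_count(df$allele_repeats, "allele_repeats", allow_zero = FALSE)
  df$allele_repeats <- as.integer(df$allele_repeats)
  class(df) <- c("str_profile", class(df))
  df
}

#' Construct a cohort mutation table
#'
#' One row per confirmed somatic mutation observation: patient, outcome group,
#' cohort (discovery = whole-exome trio patients, extension = targeted-panel
#' patients), gene, mutation identifier and its distribution status across
#' diagnosis/relapse.  Group sizes (patients sequenced, including those with
#' no mutation and hence no rows) are carried as the `group_sizes` attribute,
#' never inferred from row counts.
#'
#' @param df Data frame with columns `patient`, `group`, `cohort`, `gene`,
#'   `mutation_id`, `status`.
#' @param group_sizes Named numeric vector of patients sequenced per group,
#'   e.g. `c(relapsed = 28, non_relapsed = 30)`.
#' @return A tibble of class `cohort_mutation_table`.
#' @export
as_cohort_mutation_table <- function(df, group_sizes = NULL) {
  req <- c("patient", "group", "cohort", "gene", "mutation_id", "status")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "relapsekit_schema_error")
  }
  df <- as_tibble(df)[req]
  bad_grp <- setdiff(unique(df$group), c("relapsed", "non_relapsed"))
  if (length(bad_grp) > 0) {
    abort(paste0("unknown group: ", paste(bad_grp, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  bad_st <- setdiff(unique(df$status), STATUS_LEVELS)
  if (length(bad_st) > 0) {
    abort(paste0("unknown status: ", paste(bad_st, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  nr <- df$group == "non_relapsed"
  if (any(df$status[nr] != "diagnosis_only_nonrelapsed")) {
    abort("non-relapsed patients must have status 'diagnosis_only_nonrelapsed'",
      class = "relapsekit_value_error")
  }
  if (anyDuplicated(df[c("patient", "gene", "mutation_id")]) > 0) {
    abort("(patient, gene, mutation_id) must be unique",
      class = "relapsekit_value_error")
  }
  attr(df, "group_sizes") <- group_sizes
  class(df) <- c("cohort_mutation_table", class(df))
  df
}
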