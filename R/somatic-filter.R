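#' Quality pre-filter for variant calls
#'
#' Applies the upstream call-quality rule with strict inequalities: retained
#' calls have mapping quality > `min_mapping_quality`, base quality >
#' `min_base_quality` and variant reads > `min_var_reads` (defaults 30 / 15 /
#' 3, so a call with exactly 3 variant reads is removed).
#'
#' @param calls A `variant_calls` tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return The retained calls, order preserved.
#' @export
quality_prefilter <- function(calls, thresholds = filter_thresholds()) {
  keep <- calls$mapping_quality > thresholds$min_mapping_quality &
    calls$base_quality > thresholds$min_base_quality &
    calls$var_reads > thresholds$min_var_reads
  calls[keep, , drop = FALSE]
}

#' Remove known database variants
#'
#' Set difference on the (chrom, pos, ref, alt) key against a user-supplied
#' blacklist (e.g. common SNPs exported from dbSNP / 1000 Genomes).  An entry
#' differing in any key component — including the alt allele — does not match.
#'
#' @param calls A `variant_calls` tibble.
#' @param blacklist Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (see [read_blacklist()]).
#' @return The calls not present in the blacklist, order preserved.
#' @export
remove_known_snps <- function(calls, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(calls)
  }
  keep <- !(variant_key(calls) %in% variant_key(blacklist))
  calls[keep, , drop = FALSE]
}

#' Is an effect class protein-altering?
#'
#' @param effect Character vector of effect classes (see [effect_levels()]).
#' @return Logical vector: `TRUE` for nonsynonymous, frameshift, stopgain,
#'   in-frame indel and splice-site changes; `FALSE` for synonymous and
#'   `"other"`.
#' @export
is_protein_altering <- function(effect) {
  bad <- setdiff(unique(effect), EFFECT_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown effect class: ", paste(bad, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  effect %in% PROTEIN_ALTERING
}

vaf_of <- function(v, r) ifelse(v + r > 0, v / (v + r), 0)

# Look up remission VAF for a variant key; absent or zero-depth sites count
# as 0 (zero-depth with a warning: the site carries no remission evidence).
remission_vaf <- function(keys, cr_calls) {
  cr_key <- variant_key(cr_calls)
  idx <- match(keys, cr_key)
  v <- cr_calls$var_reads[idx]
  r <- cr_calls$ref_reads[idx]
  out <- numeric(length(keys))
  hit <- !is.na(idx)
  depth0 <- hit & (v + r) == 0
  if (any(depth0)) {
    warn(sprintf(
      "%d remission site(s) with zero depth treated as remission VAF 0",
      sum(depth0)
    ))
  }
  ok <- hit & (v + r) > 0
  out[ok] <- v[ok] / (v[ok] + r[ok])
  out
}

#' Select candidate somatic mutations from a matched trio
#'
#' Re-implements the published candidate selection on a matched
#' diagnosis/CR/relapse/donor call set.  After the quality pre-filter and
#' known-SNP removal on the tumor call sets, a variant (keyed by chrom, pos,
#' ref, alt) is a candidate iff:
#'
#' * tumor VAF >= `min_tumor_vaf` **and** tumor depth >= `min_tumor_depth`,
#'   both holding in the same sample, in the diagnosis or relapse sample
#'   (`tumor_rule = "either"`, the default) or in both (`"both"`);
#' * remission VAF < `max_remission_vaf` (a site absent from the CR table
#'   counts as 0);
#' * the effect is protein-altering ([is_protein_altering()]);
#' * the variant is absent from the donor call set — any donor presence
#'   (variant reads > 0 after the quality pre-filter) excludes it, since such
#'   calls originate from donor DNA rather than the leukemic clone.
#'
#' @param trio A [patient_trio()].
#' @param thresholds A [filter_thresholds()] object.
#' @param blacklist Optional known-variant blacklist (see [read_blacklist()]).
#' @return A tibble with one row per candidate: the variant key columns,
#'   `gene`, `effect`, per-stage VAF/depth, and `tumor_stage` (`"diagnosis"`,
#'   `"relapse"` or `"both"` — where the VAF + depth condition held).
#'   Variants excluded for donor origin are attached as the `"donor_origin"`
#'   attribute.
#' @export
call_somatic_candidates <- function(trio, thresholds = filter_thresholds(),
                                    blacklist = NULL) {
  stopifnot(inherits(trio, "patient_trio"))
  if (is.null(trio$cr) || nrow(trio$cr) == 0) {
    abort("trio has no remission (CR) calls: the remission reference is mandatory",
      class = "relapsekit_value_error")
  }
  prep <- function(calls) {
    remove_known_snps(quality_prefilter(calls, thresholds), blacklist)
  }
  diag <- prep(trio$diagnosis)
  rel <- if (!is.null(trio$relapse)) prep(trio$relapse) else trio$diagnosis[0, ]
  donor <- quality_prefilter(trio$donor, thresholds)

  tumor <- dplyr::bind_rows(
    dplyr::mutate(diag, .stage = "diagnosis"),
    dplyr::mutate(rel, .stage = "relapse")
  )
  if (nrow(tumor) == 0) {
    out <- tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character(), effect = character(),
      diagnosis_vaf = numeric(), diagnosis_depth = integer(),
      relapse_vaf = numeric(), relapse_depth = integer(),
      remission_vaf = numeric(), tumor_stage = character()
    )
    attr(out, "donor_origin") <- out
    return(out)
  }
  tumor$.key <- variant_key(tumor)
  tumor$.vaf <- vaf_of(tumor$var_reads, tumor$ref_reads)
  tumor$.depth <- tumor$var_reads + tumor$ref_reads
  tumor$.pass <- tumor$.vaf >= thresholds$min_tumor_vaf &
    tumor$.depth >= thresholds$min_tumor_depth

  per_key <- tumor |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      chrom = .data$chrom[1], pos = .data$pos[1],
      ref = .data$ref[1], alt = .data$alt[1],
      gene = .data$gene[1], effect = .data$effect[1],
      diagnosis_vaf = ifelse(any(.data$.stage == "diagnosis"),
        .data$.vaf[.data$.stage == "diagnosis"][1], NA_real_),
      diagnosis_depth = ifelse(any(.data$.stage == "diagnosis"),
        .data$.depth[.data$.stage == "diagnosis"][1], NA_integer_),
      relapse_vaf = ifelse(any(.data$.stage == "relapse"),
        .data$.vaf[.data$.stage == "relapse"][1], NA_real_),
      relapse_depth = ifelse(any(.data$.stage == "relapse"),
        .data$.depth[.data$.stage == "relapse"][1], NA_integer_),
      pass_diag = any(.data$.pass[.data$.stage == "diagnosis"]),
      pass_rel = any(.data$.pass[.data$.stage == "relapse"]),
      .groups = "drop"
    )

  tumor_ok <- if (thresholds$tumor_rule == "either") {
    per_key$pass_diag | per_key$pass_rel
  } else {
    per_key$pass_diag & per_key$pass_rel
  }
  rem_vaf <- remission_vaf(per_key$.key, trio$cr)
  coding_ok <- is_protein_altering(per_key$effect)
  donor_present <- per_key$.key %in% variant_key(donor[donor$var_reads > 0, ])

  per_key$remission_vaf <- rem_vaf
  per_key$tumor_stage <- dplyr::case_when(
    per_key$pass_diag & per_key$pass_rel ~ "both",
    per_key$pass_diag ~ "diagnosis",
    per_key$pass_rel ~ "relapse",
    TRUE ~ NA_character_
  )
  keep <- tumor_ok & rem_vaf < thresholds$max_remission_vaf & coding_ok
  candidates <- per_key[keep & !donor_present, ]
  donor_origin <- per_key[keep & donor_present, ]

  cols <- c(
    "chrom", "pos", "ref", "alt", "gene", "effect",
    "diagnosis_vaf", "diagnosis_depth", "relapse_vaf", "relapse_depth",
    "remission_vaf", "tumor_stage"
  )
  candidates <- candidates[order(candidates$chrom, candidates$pos,
    candidates$alt), cols]
  attr(candidates, "donor_origin") <- donor_origin[cols]
  candidates
}
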