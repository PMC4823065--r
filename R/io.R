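# TSV schema registry.  Each schema lists its columns and which of them must
# parse as non-negative integers / numerics.  Headers are versioned through
# the comment line written by the writers; readers skip comment lines.
TSV_SCHEMAS <- list(
  variant_calls = list(
    columns = c(
      "sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
      "var_reads", "ref_reads", "mapping_quality", "base_quality"
    ),
    integer = c("pos", "var_reads", "ref_reads"),
    numeric = c("mapping_quality", "base_quality"),
    comment = "# relapsekit variant_calls v1; pos is 1-based (VCF convention)"
  ),
  readcounts = list(
    columns = c(
      "patient", "gene", "aa_change", "stage", "blast_pct",
      "var_reads", "wt_reads"
    ),
    integer = c("var_reads", "wt_reads"),
    numeric = character(),
    comment = "# relapsekit readcounts v1; blast_pct empty for CR rows"
  ),
  str_profile = list(
    columns = c("sample_id", "locus", "allele_repeats", "height"),
    integer = "allele_repeats",
    numeric = "height",
    comment = "# relapsekit str_profile v1"
  ),
  cohort_table = list(
    columns = c("patient", "group", "cohort", "gene", "mutation_id", "status"),
    integer = character(),
    numeric = character(),
    comment = "# relapsekit cohort_table v1"
  ),
  blacklist = list(
    columns = c("chrom", "pos", "ref", "alt"),
    integer = "pos",
    numeric = character(),
    comment = "# relapsekit known-variant blacklist v1; pos is 1-based"
  )
)

read_tsv_schema <- function(path, schema_name) {
  schema <- TSV_SCHEMAS[[schema_name]]
  if (is.null(schema)) {
    abort(paste0("unknown schema: ", schema_name),
      class = "relapsekit_schema_error")
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "relapsekit_io_error")
  }
  df <- read.delim(path,
    sep = "\t", colClasses = "character", check.names = FALSE,
    comment.char = "#", na.strings = NULL, quote = "",
    blank.lines.skip = TRUE, stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(schema$columns, names(df))
  extra_cols <- setdiff(names(df), schema$columns)
  if (length(missing_cols) > 0) {
    abort(
      sprintf("%s: missing column(s): %s", path,
        paste(missing_cols, collapse = ", ")),
      class = "relapsekit_schema_error"
    )
  }
  if (length(extra_cols) > 0) {
    abort(
      sprintf("%s: unexpected column(s): %s", path,
        paste(extra_cols, collapse = ", ")),
      class = "relapsekit_schema_error"
    )
  }
  df <- as_tibble(df)[schema$columns]
  for (col in schema$integer) {
    ok <- grepl("^[0-9]+$", df[[col]])
    if (any(!ok)) {
      abort(
        sprintf("%s: column '%s' is not a non-negative integer at data line %d (value '%s')",
          path, col, which(!ok)[1], df[[col]][which(!ok)[1]]),
        class = "relapsekit_parse_error"
      )
    }
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in schema$numeric) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(val) & nzchar(df[[col]])
    if (any(bad)) {
      abort(
        sprintf("%s: column '%s' is not numeric at data line %d (value '%s')",
          path, col, which(bad)[1], df[[col]][which(bad)[1]]),
        class = "relapsekit_parse_error"
      )
    }
    df[[col]] <- val
  }
  df
}

write_tsv_schema <- function(df, path, schema_name) {
  schema <- TSV_SCHEMAS[[schema_name]]
  df <- as.data.frame(df)[schema$columns]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schema$comment, con)
  suppressWarnings(write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = ""
  ))
  invisible(path)
}

#' Read a variant call table from TSV
#'
#' @param path Path to a tab-separated file with the `variant_calls` schema
#'   (see [write_variant_table()] for the column set).  Lines starting with
#'   `#` are ignored.
#' @return A `variant_calls` tibble, row order preserved.
#' @export
read_variant_table <- function(path) {
  as_variant_calls(read_tsv_schema(path, "variant_calls"))
}

#' Write a variant call table to TSV
#'
#' Writes the versioned schema comment followed by a header and one row per
#' call.  `read_variant_table()` round-trips the file.
#'
#' @param calls A `variant_calls` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  write_tsv_schema(calls, path, "variant_calls")
}

#' Read a read-count table from TSV
#'
#' Expects columns `patient`, `gene`, `aa_change`, `stage` (one of
#' `diagnosis`, `CR`, `relapse`), `blast_pct`, `var_reads`, `wt_reads`.
#' `blast_pct` must be empty exactly for CR rows: remission samples are never
#' blast-adjusted, and absence is encoded explicitly rather than as 0 or 100.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `blast_pct` numeric (`NA` for CR rows).
#' @export
read_readcount_table <- function(path) {
  df <- read_tsv_schema(path, "readcounts")
  bad_stage <- setdiff(unique(df$stage), STAGE_LEVELS)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown stage: ", paste(bad_stage, collapse = ", ")),
      class = "relapsekit_value_error")
  }
  blast <- suppressWarnings(as.numeric(df$blast_pct))
  bad <- is.na(blast) & nzchar(df$blast_pct)
  if (any(bad)) {
    abort(
      sprintf("%s: blast_pct not numeric at data line %d", path, which(bad)[1]),
      class = "relapsekit_parse_error"
    )
  }
  df$blast_pct <- blast
  if (any(!is.na(df$blast_pct) & df$stage == "CR")) {
    abort("CR rows must have empty blast_pct", class = "relapsekit_value_error")
  }
  if (any(is.na(df$blast_pct) & df$stage != "CR")) {
    abort("tumor-stage rows must carry blast_pct",
      class = "relapsekit_value_error")
  }
  df
}

#' Read an STR peak-height profile from TSV
#'
#' @param path Path to a TSV file with columns `sample_id`, `locus`,
#'   `allele_repeats`, `height`.
#' @return An `str_profile` tibble.
#' @export
read_str_profile <- function(path) {
  as_str_profile(read_tsv_schema(path, "str_profile"))
}

#' Read a cohort mutation table from TSV
#'
#' @param path Path to a TSV file with columns `patient`, `group`, `cohort`,
#'   `gene`, `mutation_id`, `status`.
#' @param group_sizes Optional named vector of sequenced patients per group;
#'   stored as table metadata (see [as_cohort_mutation_table()]).
#' @return A `cohort_mutation_table` tibble.
#' @export
read_cohort_table <- function(path, group_sizes = NULL) {
  as_cohort_mutation_table(read_tsv_schema(path, "cohort_table"), group_sizes)
}

#' Read a known-variant blacklist from TSV
#'
#' The blacklist (e.g. an export of common database SNPs) is user-supplied;
#' matching is exact on (chrom, pos, ref, alt).
#'
#' @param path Path to a TSV file with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A tibble of blacklisted variant keys.
#' @export
read_blacklist <- function(path) {
  read_tsv_schema(path, "blacklist")
}

#' Import variant calls from a minimal VCF
#'
#' Convenience importer for VCF 4.x files carrying per-sample allelic depths
#' (`AD` FORMAT field).  Multi-allelic records are expanded to one call per
#' ALT allele with the matching AD entry; positions stay 1-based.  This is a
#' thin layer over `vcfR` and deliberately supports nothing beyond AD-based
#' read counts plus an optional INFO key naming the effect class.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample Sample name as given in the VCF header.
#' @param effect_info_key Optional INFO key whose value is one of
#'   [effect_levels()]; unknown or absent values become `"other"`.
#' @return A `variant_calls` tibble.
#' @export
import_vcf_minimal <- function(path, sample, effect_info_key = NULL) {
  rlang::check_installed("vcfR")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(as_variant_calls(tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      effect = character(), var_reads = integer(), ref_reads = integer(),
      mapping_quality = numeric(), base_quality = numeric()
    )))
  }
  samples <- colnames(vcf@gt)[-1]
  if (!sample %in% samples) {
    abort(sprintf("sample '%s' not in VCF (has: %s)", sample,
      paste(samples, collapse = ", ")), class = "relapsekit_value_error")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample, drop = TRUE]
  if (all(is.na(ad))) {
    abort("VCF has no AD FORMAT values for this sample",
      class = "relapsekit_parse_error")
  }
  effect <- rep("other", nrow(fix))
  if (!is.null(effect_info_key)) {
    info_val <- vcfR::extract.info(vcf, element = effect_info_key)
    effect <- ifelse(info_val %in% EFFECT_LEVELS, info_val, "other")
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (is.na(ad[i])) {
      abort(sprintf("missing AD at record %s:%s", fix$CHROM[i], fix$POS[i]),
        class = "relapsekit_parse_error")
    }
    depths <- as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]])
    if (length(depths) != length(alts) + 1L || anyNA(depths)) {
      abort(sprintf("malformed AD '%s' at record %s:%s", ad[i],
        fix$CHROM[i], fix$POS[i]), class = "relapsekit_parse_error")
    }
    out[[i]] <- tibble(
      sample_id = sample,
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      gene = NA_character_,
      effect = effect[i],
      var_reads = depths[-1L],
      ref_reads = depths[1L],
      mapping_quality = NA_real_,
      base_quality = NA_real_
    )
  }
  as_variant_calls(dplyr::bind_rows(out))
}

#' Load a packaged study table
#'
#' The package ships machine-readable transcriptions of the published study's
#' printed tables, used as fixtures and as worked-example inputs:
#'
#' * `"table1"` — candidate relapse-associated mutated genes for the three
#'   whole-exome trio patients, long format (`patient`, `category`, `gene`).
#' * `"table2"` — recurring gene mutations across the discovery and extension
#'   cohorts as a [as_cohort_mutation_table()] (30 mutation records over 10
#'   genes), with group sizes (31 relapsed / 30 non-relapsed overall) and
#'   per-cohort sizes attached as attributes (`group_sizes`,
#'   `cohort_group_sizes`).
#' * `"table3"` — per-mutation read counts for the trio patients, long format
#'   with one row per (mutation, stage): `var_reads`, `wt_reads`, `blast_pct`
#'   (`NA` for CR), the printed `%Variant in tumor` value (`printed_pct`), and
#'   a `formula_discordant` flag marking the two printed cells that disagree
#'   with the blast-adjustment formula (stored as printed, not corrected).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A tibble (typed per the table, see above).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "relapsekit",
    mustWork = TRUE)
  switch(name,
    table1 = {
      df <- read.delim(path("table1_mutated_genes.tsv"),
        stringsAsFactors = FALSE, comment.char = "#")
      as_tibble(df)
    },
    table2 = {
      df <- read.delim(path("table2_cohort_mutations.tsv"),
        stringsAsFactors = FALSE, comment.char = "#")
      tab <- as_cohort_mutation_table(
        df,
        group_sizes = c(relapsed = 31, non_relapsed = 30)
      )
      attr(tab, "cohort_group_sizes") <- tibble(
        cohort = c("discovery", "extension", "extension"),
        group = c("relapsed", "relapsed", "non_relapsed"),
        n = c(3L, 28L, 30L)
      )
      tab$aa_change <- df$aa_change
      tab$effect <- df$effect
      tab
    },
    table3 = {
      df <- read.delim(path("table3_readcounts.tsv"),
        stringsAsFactors = FALSE, comment.char = "#",
        na.strings = ""
      )
      df$blast_pct <- as.numeric(df$blast_pct)
      df$formula_discordant <- as.logical(df$formula_discordant)
      as_tibble(df)
    }
  )
}
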