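# Independent oracles and small data builders shared across the suite.
# Oracles are written as direct transcriptions of the rules, independent of
# the package's implementation paths.

# Brute-force candidate-selection oracle: one flat predicate evaluated per
# variant key over the whole trio, no staging or grouping machinery.
oracle_somatic_candidates <- function(trio, t = filter_thresholds(),
                                      blacklist = NULL) {
  bl_keys <- if (is.null(blacklist)) character() else {
    paste(blacklist$chrom, blacklist$pos, blacklist$ref, blacklist$alt, sep = ":")
  }
  key_of <- function(df, i) {
    paste(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], sep = ":")
  }
  qual_ok <- function(df, i) {
    df$mapping_quality[i] > t$min_mapping_quality &&
      df$base_quality[i] > t$min_base_quality &&
      df$var_reads[i] > t$min_var_reads
  }
  tumor_pass <- function(df, key) {
    for (i in seq_len(nrow(df))) {
      if (key_of(df, i) == key && qual_ok(df, i) &&
        !(key %in% bl_keys)) {
        depth <- df$var_reads[i] + df$ref_reads[i]
        if (depth >= t$min_tumor_depth &&
          depth > 0 && df$var_reads[i] / depth >= t$min_tumor_vaf) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tumor_seen <- function(df, key) {
    for (i in seq_len(nrow(df))) {
      if (key_of(df, i) == key && qual_ok(df, i) && !(key %in% bl_keys)) {
        return(TRUE)
      }
    }
    FALSE
  }
  cr_vaf <- function(key) {
    df <- trio$cr
    for (i in seq_len(nrow(df))) {
      if (key_of(df, i) == key) {
        depth <- df$var_reads[i] + df$ref_reads[i]
        return(if (depth == 0) 0 else df$var_reads[i] / depth)
      }
    }
    0
  }
  donor_present <- function(key) {
    df <- trio$donor
    for (i in seq_len(nrow(df))) {
      if (key_of(df, i) == key && qual_ok(df, i) && df$var_reads[i] > 0) {
        return(TRUE)
      }
    }
    FALSE
  }
  all_tumor <- rbind(as.data.frame(trio$diagnosis),
    if (!is.null(trio$relapse)) as.data.frame(trio$relapse))
  keys <- unique(paste(all_tumor$chrom, all_tumor$pos, all_tumor$ref,
    all_tumor$alt, sep = ":"))
  out <- character()
  for (key in keys) {
    seen <- tumor_seen(trio$diagnosis, key) ||
      (!is.null(trio$relapse) && tumor_seen(trio$relapse, key))
    if (!seen) next
    pd <- tumor_pass(trio$diagnosis, key)
    pr <- if (is.null(trio$relapse)) FALSE else tumor_pass(trio$relapse, key)
    pass <- if (t$tumor_rule == "either") pd || pr else pd && pr
    i <- which(paste(all_tumor$chrom, all_tumor$pos, all_tumor$ref,
      all_tumor$alt, sep = ":") == key)[1]
    coding <- all_tumor$effect[i] %in% c(
      "nonsynonymous", "frameshift", "stopgain", "inframe_indel", "splice_site"
    )
    if (pass && cr_vaf(key) < t$max_remission_vaf && coding &&
      !donor_present(key)) {
      out <- c(out, key)
    }
  }
  sort(out)
}

# Two-sided Fisher p-value by explicit enumeration with dhyper (the
# implementation under test uses its own log-factorial arithmetic).
oracle_fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# Minimal variant-call table builder with pass-everything defaults.
make_calls <- function(n = 0, sample_id = "S", chrom = "chr1",
                       pos = seq_len(max(n, 1)), ref = "A", alt = "G",
                       gene = "GENE1", effect = "nonsynonymous",
                       var_reads = 30L, ref_reads = 70L,
                       mapping_quality = 60, base_quality = 30) {
  if (n == 0) {
    return(as_variant_calls(tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character(),
      effect = character(), var_reads = integer(), ref_reads = integer(),
      mapping_quality = numeric(), base_quality = numeric()
    )))
  }
  as_variant_calls(tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos[seq_len(n)], ref = ref,
    alt = alt, gene = gene, effect = effect, var_reads = var_reads,
    ref_reads = ref_reads, mapping_quality = mapping_quality,
    base_quality = base_quality
  ))
}

# Randomized trio spanning the filter's decision boundaries, for the
# oracle-equivalence property.
random_trio <- function(n_variants = 50, seed = 1) {
  withr::with_seed(seed, {
    keys <- tibble::tibble(
      chrom = paste0("chr", sample(1:22, n_variants, replace = TRUE)),
      pos = sample(1e6, n_variants),
      ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      gene = paste0("G", seq_len(n_variants)),
      effect = sample(effect_levels(), n_variants, replace = TRUE)
    )
    rand_calls <- function(sample_id, present_prob = 0.8) {
      present <- runif(n_variants) < present_prob
      df <- keys[present, ]
      k <- nrow(df)
      df$sample_id <- sample_id
      df$var_reads <- sample(0:40, k, replace = TRUE)
      df$ref_reads <- sample(0:80, k, replace = TRUE)
      df$mapping_quality <- runif(k, 20, 60)
      df$base_quality <- runif(k, 10, 30)
      # keep at least one read so VAF is defined where needed
      df$ref_reads[df$var_reads + df$ref_reads == 0] <- 1L
      as_variant_calls(df)
    }
    cr <- rand_calls("P-CR", 0.9)
    # low-level remission evidence around the 0.5% bound
    cr$var_reads <- sample(0:2, nrow(cr), replace = TRUE)
    cr$ref_reads <- sample(c(50L, 200L, 400L), nrow(cr), replace = TRUE)
    blacklist <- keys[sample(n_variants, ceiling(n_variants / 5)),
      c("chrom", "pos", "ref", "alt")]
    list(
      trio = patient_trio(
        patient = "P",
        diagnosis = rand_calls("P-D"),
        cr = cr,
        relapse = rand_calls("P-TR"),
        donor = rand_calls("P-DONOR", 0.3),
        group = "relapsed"
      ),
      blacklist = blacklist
    )
  })
}

# Tiny STR profile builder: one row per (locus, allele, height).
make_profile <- function(sample_id, ...) {
  spec <- list(...)
  rows <- lapply(names(spec), function(locus) {
    al <- spec[[locus]]
    tibble::tibble(
      sample_id = sample_id, locus = locus,
      allele_repeats = as.integer(names(al)), height = unname(al)
    )
  })
  as_str_profile(dplyr::bind_rows(rows))
}
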