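#' Simulation parameters
#'
#' One object fixing every knob (and all randomness, via `seed`) of the
#' synthetic cohort generator.  Defaults emulate the sequencing study the
#' package reproduces: ~100x mean exome coverage with a negative-binomial
#' spread giving per-site depths of roughly 15-170 reads, and multiplicative
#' STR peak noise of 10%.
#'
#' @param mean_depth Mean sequencing depth per site (default 100).
#' @param depth_dispersion Negative-binomial dispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 means fixed depth. Default 0.15.
#' @param n_known_snp_contaminants Number of germline common-SNP variants
#'   added to every patient sample (default 20); these are returned as the
#'   blacklist.
#' @param n_donor_variants Number of donor-origin variants appearing in the
#'   relapse and donor samples (default 5).
#' @param str_noise_cv Coefficient of variation of the multiplicative
#'   lognormal peak-height noise (default 0.1).
#' @param stutter_rate Height of the stutter peak at repeat - 1 as a fraction
#'   of the parent peak (default 0 = off).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mean_depth = 100, depth_dispersion = 0.15,
                       n_known_snp_contaminants = 20L, n_donor_variants = 5L,
                       str_noise_cv = 0.1, stutter_rate = 0, seed = 1L) {
  stopifnot(
    mean_depth > 0, depth_dispersion >= 0, n_known_snp_contaminants >= 0,
    n_donor_variants >= 0, str_noise_cv >= 0,
    stutter_rate >= 0, stutter_rate <= 1
  )
  structure(
    list(
      mean_depth = mean_depth, depth_dispersion = depth_dispersion,
      n_known_snp_contaminants = as.integer(n_known_snp_contaminants),
      n_donor_variants = as.integer(n_donor_variants),
      str_noise_cv = str_noise_cv, stutter_rate = stutter_rate,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Construct a clone model
#'
#' A clone tree under the perfect-phylogeny assumption: each clone's mutation
#' set is a superset of its parent's, and per-stage clone fractions (of tumor
#' cells) sum to at most 1.  Mutations are heterozygous diploid by default,
#' so a mutation carried by a fraction f of tumor cells in a sample with
#' blast fraction B has expected VAF f * B / 2; `copy_multiplier` rescales
#' that factor per clone for non-diploid scenarios (1 = heterozygous).
#'
#' @param clones Data frame with columns `id`, `parent` (`NA` for a root),
#'   `mutations` (list-column of mutation-id character vectors, cumulative
#'   along the tree), `fraction_at_diagnosis`, `fraction_at_relapse`, and
#'   optionally `copy_multiplier` (default 1).
#' @param blast_pct_diagnosis,blast_pct_relapse Blast percentages of the two
#'   tumor samples, in (0, 100].
#' @param residual_cr_fraction Fraction of leukemic cells persisting in the
#'   remission sample (default 0).
#' @return A list of class `clone_model`.
#' @export
clone_model <- function(clones, blast_pct_diagnosis = 90,
                        blast_pct_relapse = 90, residual_cr_fraction = 0) {
  clones <- as_tibble(clones)
  if (!"copy_multiplier" %in% names(clones)) clones$copy_multiplier <- 1
  check_fraction(clones$fraction_at_diagnosis, "fraction_at_diagnosis")
  check_fraction(clones$fraction_at_relapse, "fraction_at_relapse")
  check_fraction(residual_cr_fraction, "residual_cr_fraction")
  stopifnot(
    blast_pct_diagnosis > 0, blast_pct_diagnosis <= 100,
    blast_pct_relapse > 0, blast_pct_relapse <= 100
  )
  if (sum(clones$fraction_at_diagnosis) > 1 + 1e-9 ||
    sum(clones$fraction_at_relapse) > 1 + 1e-9) {
    abort("per-stage clone fractions must sum to <= 1",
      class = "relapsekit_value_error")
  }
  for (i in seq_len(nrow(clones))) {
    p <- clones$parent[i]
    if (!is.na(p)) {
      j <- match(p, clones$id)
      if (is.na(j)) {
        abort(sprintf("clone '%s' has unknown parent '%s'", clones$id[i], p),
          class = "relapsekit_value_error")
      }
      if (!all(clones$mutations[[j]] %in% clones$mutations[[i]])) {
        abort(sprintf(
          "perfect phylogeny violated: clone '%s' lacks mutations of parent '%s'",
          clones$id[i], p
        ), class = "relapsekit_value_error")
      }
    }
  }
  structure(
    list(
      clones = clones,
      blast_pct_diagnosis = blast_pct_diagnosis,
      blast_pct_relapse = blast_pct_relapse,
      residual_cr_fraction = residual_cr_fraction
    ),
    class = "clone_model"
  )
}

# Cell fraction carrying each mutation at a stage: sum of fractions of the
# clones whose mutation set contains it.
mutation_cell_fractions <- function(model, stage = c("diagnosis", "relapse")) {
  stage <- match.arg(stage)
  frac_col <- if (stage == "diagnosis") "fraction_at_diagnosis" else
    "fraction_at_relapse"
  muts <- unique(unlist(model$clones$mutations))
  vapply(muts, function(m) {
    carriers <- vapply(model$clones$mutations, function(s) m %in% s, logical(1))
    sum(model$clones[[frac_col]][carriers])
  }, numeric(1))
}

mutation_copy_multiplier <- function(model) {
  muts <- unique(unlist(model$clones$mutations))
  vapply(muts, function(m) {
    carriers <- vapply(model$clones$mutations, function(s) m %in% s, logical(1))
    # multiplier of the first carrying clone; clones sharing a mutation share
    # its copy state under perfect phylogeny
    model$clones$copy_multiplier[which(carriers)[1]]
  }, numeric(1))
}

#' Default clone models for the three relapse patterns
#'
#' * `subclone_survival` — a founder clone and a subclone (founder mutations
#'   plus private ones) present at both stages with fractions flipping from
#'   0.8/0.2 at diagnosis to 0.2/0.8 at relapse: every mutation is shared.
#' * `common_progenitor` — a diagnosis clone and a relapse clone, each adding
#'   private mutations to a common progenitor set: shared, diagnosis-specific
#'   and relapse-specific mutations all non-empty.
#' * `second_malignancy` — two unrelated clones with disjoint mutation sets.
#'
#' @param pattern One of `"subclone_survival"`, `"common_progenitor"`,
#'   `"second_malignancy"`.
#' @param n_shared,n_private Number of trunk mutations and of mutations
#'   private to each derived clone (defaults 4 and 3).
#' @param blast_pct_diagnosis,blast_pct_relapse,residual_cr_fraction Passed
#'   to [clone_model()].
#' @return A `clone_model`.
#' @export
pattern_clone_model <- function(pattern = c("subclone_survival",
                                            "common_progenitor",
                                            "second_malignancy"),
                                n_shared = 4L, n_private = 3L,
                                blast_pct_diagnosis = 90,
                                blast_pct_relapse = 90,
                                residual_cr_fraction = 0) {
  pattern <- match.arg(pattern)
  stopifnot(n_shared >= 1, n_private >= 1)
  mut_ids <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  clones <- switch(pattern,
    subclone_survival = tibble(
      id = c("founder", "subclone"),
      parent = c(NA, "founder"),
      mutations = list(
        mut_ids("m", n_shared),
        c(mut_ids("m", n_shared), mut_ids("s", n_private))
      ),
      fraction_at_diagnosis = c(0.8, 0.2),
      fraction_at_relapse = c(0.2, 0.8)
    ),
    common_progenitor = tibble(
      id = c("progenitor", "diagnosis_clone", "relapse_clone"),
      parent = c(NA, "progenitor", "progenitor"),
      mutations = list(
        mut_ids("m", n_shared),
        c(mut_ids("m", n_shared), mut_ids("d", n_private)),
        c(mut_ids("m", n_shared), mut_ids("r", n_private))
      ),
      fraction_at_diagnosis = c(0, 1, 0),
      fraction_at_relapse = c(0, 0, 1)
    ),
    second_malignancy = tibble(
      id = c("primary_clone", "second_clone"),
      parent = c(NA_character_, NA_character_),
      mutations = list(mut_ids("d", n_shared), mut_ids("r", n_shared)),
      fraction_at_diagnosis = c(1, 0),
      fraction_at_relapse = c(0, 1)
    )
  )
  clone_model(clones, blast_pct_diagnosis, blast_pct_relapse,
    residual_cr_fraction)
}

sample_depth <- function(n, params) {
  if (params$depth_dispersion == 0) {
    rep(round(params$mean_depth), n)
  } else {
    rnbinom(n, size = 1 / params$depth_dispersion, mu = params$mean_depth)
  }
}

sim_call_row <- function(sample_id, chrom, pos, ref, alt, gene, effect,
                         var_reads, ref_reads) {
  tibble(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, effect = effect, var_reads = var_reads,
    ref_reads = ref_reads,
    # qualities drawn clear of the default cutoffs; the quality pre-filter
    # is exercised separately with adversarial calls in the test suite
    mapping_quality = runif(length(pos), 40, 60),
    base_quality = runif(length(pos), 25, 35)
  )
}

#' Simulate one matched patient trio with known ground truth
#'
#' Generates a clone model for the requested relapse pattern, then samples
#' per-site read counts for the diagnosis, remission (CR), relapse and donor
#' samples: depth is negative-binomial, and variant reads are binomial with
#' success probability `blast_fraction * cell_fraction / 2` (heterozygous
#' diploid).  CR variant reads use `residual_cr_fraction * diagnosis cell
#' fraction / 2` (all zero at the default residual fraction of 0).  Germline
#' common-SNP contaminants (VAF 1/2 in every patient sample; returned as the
#' blacklist) and donor-origin variants (VAF 1/2 in the relapse and donor
#' samples only, mimicking donor cells in the post-transplant marrow) are
#' added so the somatic filter has something to remove.
#'
#' @param pattern Relapse pattern, see [pattern_clone_model()].
#' @param params A [sim_params()] object; its `seed` fixes all randomness.
#' @param model Optional [clone_model()] overriding the pattern default.
#' @return A list of class `sim_patient` with elements `model`, `trio`
#'   (a [patient_trio()]), `readcounts` (tumor/CR read-count table in the
#'   [read_readcount_table()] layout), `blacklist`, and `truth` (per-mutation
#'   tibble of cell fractions and true status).
#' @export
simulate_patient <- function(pattern = c("subclone_survival",
                                         "common_progenitor",
                                         "second_malignancy"),
                             params = sim_params(), model = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(model)) {
    model <- pattern_clone_model(pattern)
  }
  withr::with_seed(params$seed, {
    frac_d <- mutation_cell_fractions(model, "diagnosis")
    frac_r <- mutation_cell_fractions(model, "relapse")
    cm <- mutation_copy_multiplier(model)
    muts <- names(frac_d)
    n <- length(muts)
    truth <- tibble(
      mutation_id = muts,
      gene = paste0("GENE_", toupper(muts)),
      effect = rep_len(c("nonsynonymous", "frameshift", "nonsynonymous",
        "stopgain", "nonsynonymous", "inframe_indel"), n),
      chrom = paste0("chr", rep_len(1:22, n)),
      pos = 1000000L + seq_len(n) * 1000L,
      ref = rep_len(c("A", "C", "G", "T"), n),
      alt = rep_len(c("G", "T", "A", "C"), n),
      cell_fraction_diagnosis = unname(frac_d),
      cell_fraction_relapse = unname(frac_r),
      status = mutation_status(frac_d > 0, frac_r > 0)
    )
    bd <- model$blast_pct_diagnosis / 100
    br <- model$blast_pct_relapse / 100
    p_diag <- pmin(1, bd * frac_d * cm / 2)
    p_rel <- pmin(1, br * frac_r * cm / 2)
    p_cr <- pmin(1, model$residual_cr_fraction * frac_d * cm / 2)

    draw_stage <- function(p) {
      depth <- sample_depth(n, params)
      v <- rbinom(n, depth, p)
      list(var = v, ref = depth - v)
    }
    d <- draw_stage(p_diag)
    r <- draw_stage(p_rel)
    cr <- draw_stage(p_cr)

    somatic_calls <- function(sample_id, drawn) {
      sim_call_row(sample_id, truth$chrom, truth$pos, truth$ref, truth$alt,
        truth$gene, truth$effect, drawn$var, drawn$ref)
    }
    pt <- "SIM001"
    calls_d <- somatic_calls(paste0(pt, "-D"), d)
    calls_r <- somatic_calls(paste0(pt, "-TR"), r)
    calls_cr <- somatic_calls(paste0(pt, "-CR"), cr)
    calls_dn <- somatic_calls(paste0(pt, "-DONOR"),
      list(var = rep(0L, n), ref = sample_depth(n, params)))

    # germline common-SNP contaminants: VAF 1/2 in all patient samples
    n_snp <- params$n_known_snp_contaminants
    blacklist <- tibble(
      chrom = paste0("chr", rep_len(1:22, n_snp)),
      pos = 5000000L + seq_len(n_snp) * 777L,
      ref = rep_len(c("C", "T", "A", "G"), n_snp),
      alt = rep_len(c("T", "C", "G", "A"), n_snp)
    )[seq_len(n_snp), ]
    germline <- function(sample_id) {
      depth <- sample_depth(n_snp, params)
      v <- rbinom(n_snp, depth, 0.5)
      sim_call_row(sample_id, blacklist$chrom, blacklist$pos, blacklist$ref,
        blacklist$alt, paste0("SNPGENE_", seq_len(n_snp)),
        rep_len("nonsynonymous", n_snp), v, depth - v)
    }
    if (n_snp > 0) {
      calls_d <- dplyr::bind_rows(calls_d, germline(paste0(pt, "-D")))
      calls_r <- dplyr::bind_rows(calls_r, germline(paste0(pt, "-TR")))
      calls_cr <- dplyr::bind_rows(calls_cr, germline(paste0(pt, "-CR")))
    }

    # donor-origin variants: donor germline, visible in relapse marrow
    n_dv <- params$n_donor_variants
    if (n_dv > 0) {
      dv <- tibble(
        chrom = paste0("chr", rep_len(1:22, n_dv)),
        pos = 9000000L + seq_len(n_dv) * 333L,
        ref = rep_len(c("G", "A", "T", "C"), n_dv),
        alt = rep_len(c("A", "G", "C", "T"), n_dv)
      )
      donor_like <- function(sample_id) {
        depth <- sample_depth(n_dv, params)
        v <- rbinom(n_dv, depth, 0.5)
        sim_call_row(sample_id, dv$chrom, dv$pos, dv$ref, dv$alt,
          paste0("DONORGENE_", seq_len(n_dv)),
          rep_len("nonsynonymous", n_dv), v, depth - v)
      }
      calls_r <- dplyr::bind_rows(calls_r, donor_like(paste0(pt, "-TR")))
      calls_dn <- dplyr::bind_rows(calls_dn, donor_like(paste0(pt, "-DONOR")))
    }

    trio <- patient_trio(
      patient = pt,
      diagnosis = calls_d, cr = calls_cr, relapse = calls_r, donor = calls_dn,
      group = "relapsed"
    )
    readcounts <- dplyr::bind_rows(
      tibble(patient = pt, gene = truth$gene, aa_change = truth$mutation_id,
        stage = "diagnosis", blast_pct = model$blast_pct_diagnosis,
        var_reads = d$var, wt_reads = d$ref),
      tibble(patient = pt, gene = truth$gene, aa_change = truth$mutation_id,
        stage = "relapse", blast_pct = model$blast_pct_relapse,
        var_reads = r$var, wt_reads = r$ref),
      tibble(patient = pt, gene = truth$gene, aa_change = truth$mutation_id,
        stage = "CR", blast_pct = NA_real_,
        var_reads = cr$var, wt_reads = cr$ref)
    )
    structure(
      list(
        pattern = pattern, model = model, trio = trio,
        readcounts = readcounts, blacklist = blacklist, truth = truth
      ),
      class = "sim_patient"
    )
  })
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) {
    rep(1, n)
  } else {
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean 1
  }
}

#' The 15-locus STR panel used for chimerism genotyping
#'
#' Locus names of the autosomal markers in the Identifiler kit.
#'
#' @return Character vector of 15 locus names.
#' @export
default_str_panel <- function() {
  c(
    "D8S1179", "D21S11", "D7S820", "CSF1PO", "D3S1358", "TH01", "D13S317",
    "D16S539", "D2S1338", "D19S433", "vWA", "TPOX", "D18S51", "D5S818", "FGA"
  )
}

#' Random patient/donor STR genotype templates
#'
#' Draws heterozygous two-allele genotypes per locus for an unrelated
#' patient/donor pair, biased so that most loci carry at least one
#' patient-specific and one donor-specific allele within one repeat unit —
#' the configuration the chimerism estimator can use.
#'
#' @param params A [sim_params()]; `seed` fixes the genotypes.
#' @param loci Locus names (default [default_str_panel()]).
#' @param base_height Unmixed peak height in RFU (default 2000).  Equal
#'   heights across alleles make peak height exactly proportional to cell
#'   fraction, so noise-free mixtures are recovered exactly.
#' @param height_jitter Relative spread of per-allele amplification
#'   efficiency (default 0); set e.g. 0.2 to stress the estimator with
#'   unequal efficiencies.
#' @return List with `patient` and `donor` `str_profile` tibbles.
#' @export
random_str_templates <- function(params = sim_params(),
                                 loci = default_str_panel(),
                                 base_height = 2000, height_jitter = 0) {
  stopifnot(height_jitter >= 0, height_jitter < 1)
  withr::with_seed(params$seed + 1L, {
    jitter <- function(n) {
      if (height_jitter == 0) rep(1, n) else
        runif(n, 1 - height_jitter, 1 + height_jitter)
    }
    rows_p <- list()
    rows_d <- list()
    for (locus in loci) {
      a <- sample(8:20, 1)
      patient_alleles <- c(a, a + sample(2:5, 1))
      donor_alleles <- c(a + 1, a + sample(6:9, 1))
      rows_p[[locus]] <- tibble(
        sample_id = "PATIENT_CR", locus = locus,
        allele_repeats = patient_alleles,
        height = base_height * jitter(2)
      )
      rows_d[[locus]] <- tibble(
        sample_id = "DONOR", locus = locus,
        allele_repeats = donor_alleles,
        height = base_height * jitter(2)
      )
    }
    list(
      patient = as_str_profile(dplyr::bind_rows(rows_p)),
      donor = as_str_profile(dplyr::bind_rows(rows_d))
    )
  })
}

#' Simulate an STR mixture experiment
#'
#' Builds the three electropherogram profiles of a chimerism measurement:
#' the pure CR (patient) sample, the pure donor sample, and the relapse
#' sample as a mixture in which each allele's peak height is its template
#' height scaled by the owning population's fraction, with multiplicative
#' lognormal noise (`str_noise_cv`).  Alleles shared by patient and donor
#' receive both contributions.  Optional stutter adds a peak one repeat unit
#' below each true allele at `stutter_rate` times the parent height.
#'
#' @param patient_alleles,donor_alleles Template `str_profile` tibbles of
#'   pure patient and donor samples (see [random_str_templates()]).
#' @param patient_fraction Fraction of patient cells in the relapse sample,
#'   in \[0, 1\].
#' @param params A [sim_params()]; `seed` fixes the noise.
#' @return List of class `sim_str_mixture` with `cr`, `donor`, `relapse`
#'   `str_profile` tibbles and `patient_fraction` (the ground truth).
#' @export
simulate_str_mixture <- function(patient_alleles, donor_alleles,
                                 patient_fraction, params = sim_params()) {
  check_fraction(patient_fraction, "patient_fraction")
  patient_alleles <- as_str_profile(patient_alleles)
  donor_alleles <- as_str_profile(donor_alleles)
  withr::with_seed(params$seed, {
    noisy <- function(h) h * lognormal_noise(length(h), params$str_noise_cv)
    cr <- patient_alleles
    cr$sample_id <- "CR"
    cr$height <- noisy(cr$height)
    donor <- donor_alleles
    donor$sample_id <- "DONOR"
    donor$height <- noisy(donor$height)

    loci <- union(unique(patient_alleles$locus), unique(donor_alleles$locus))
    uninformative <- character()
    rows <- list()
    for (locus in loci) {
      pa <- patient_alleles[patient_alleles$locus == locus, ]
      da <- donor_alleles[donor_alleles$locus == locus, ]
      if (length(setdiff(pa$allele_repeats, da$allele_repeats)) == 0 ||
        length(setdiff(da$allele_repeats, pa$allele_repeats)) == 0) {
        uninformative <- c(uninformative, locus)
      }
      alleles <- sort(union(pa$allele_repeats, da$allele_repeats))
      h <- vapply(alleles, function(al) {
        hp <- sum(pa$height[pa$allele_repeats == al])
        hd <- sum(da$height[da$allele_repeats == al])
        hp * patient_fraction + hd * (1 - patient_fraction)
      }, numeric(1))
      keep <- h > 0
      alleles <- alleles[keep]
      h <- noisy(h[keep])
      if (params$stutter_rate > 0 && length(alleles) > 0) {
        st_al <- alleles - 1L
        st_h <- h * params$stutter_rate
        for (k in seq_along(st_al)) {
          hit <- match(st_al[k], alleles)
          if (!is.na(hit)) {
            h[hit] <- h[hit] + st_h[k]
          } else {
            alleles <- c(alleles, st_al[k])
            h <- c(h, st_h[k])
          }
        }
        ord <- order(alleles)
        alleles <- alleles[ord]
        h <- h[ord]
      }
      if (length(alleles) > 0) {
        rows[[locus]] <- tibble(
          sample_id = "RELAPSE", locus = locus,
          allele_repeats = as.integer(alleles), height = h
        )
      }
    }
    if (length(uninformative) > 0) {
      warn(paste0(
        "loci without both patient- and donor-specific alleles (uninformative): ",
        paste(uninformative, collapse = ", ")
      ))
    }
    structure(
      list(
        cr = cr, donor = donor,
        relapse = as_str_profile(dplyr::bind_rows(rows)),
        patient_fraction = patient_fraction
      ),
      class = "sim_str_mixture"
    )
  })
}

#' Simulate a cohort mutation table
#'
#' Per patient and gene, an independent Bernoulli draw decides whether the
#' patient carries a mutation in that gene (probability `relapse_mut_prob`
#' or `nonrelapse_mut_prob` by group).  Relapsed patients' mutations receive
#' a distribution status drawn from `status_probs`; non-relapsed patients'
#' mutations are diagnosis-only by definition.
#'
#' @param n_relapsed,n_nonrelapsed Number of patients per outcome group.
#' @param gene_effects Named list: for each gene, a list or vector with
#'   `relapse_mut_prob` and `nonrelapse_mut_prob` in \[0, 1\].
#' @param params A [sim_params()]; `seed` fixes the draws.
#' @param status_probs Probabilities of `diagnosis_specific`, `shared`,
#'   `relapse_specific` for relapsed patients' mutations (default uniform).
#' @return A [as_cohort_mutation_table()] with `group_sizes` metadata; the
#'   table may have zero rows if no patient draws a mutation.
#' @export
simulate_cohort <- function(n_relapsed, n_nonrelapsed, gene_effects,
                            params = sim_params(),
                            status_probs = c(1, 1, 1) / 3) {
  stopifnot(n_relapsed >= 0, n_nonrelapsed >= 0)
  stopifnot(abs(sum(status_probs) - 1) < 1e-9)
  for (g in names(gene_effects)) {
    ge <- gene_effects[[g]]
    check_fraction(unlist(ge[c("relapse_mut_prob", "nonrelapse_mut_prob")]),
      paste0("gene_effects$", g))
  }
  withr::with_seed(params$seed, {
    patients <- tibble(
      patient = c(
        sprintf("SIMR%03d", seq_len(n_relapsed)),
        sprintf("SIMN%03d", seq_len(n_nonrelapsed))
      ),
      group = rep(c("relapsed", "non_relapsed"), c(n_relapsed, n_nonrelapsed))
    )
    rows <- list()
    for (g in names(gene_effects)) {
      ge <- gene_effects[[g]]
      p <- ifelse(patients$group == "relapsed",
        ge[["relapse_mut_prob"]], ge[["nonrelapse_mut_prob"]])
      hit <- runif(nrow(patients)) < p
      if (!any(hit)) next
      mut <- patients[hit, ]
      mut$gene <- g
      mut$mutation_id <- sprintf("sim_%s_%s", g, mut$patient)
      mut$status <- ifelse(mut$group == "non_relapsed",
        "diagnosis_only_nonrelapsed",
        sample(c("diagnosis_specific", "shared", "relapse_specific"),
          nrow(mut), replace = TRUE, prob = status_probs))
      rows[[g]] <- mut
    }
    df <- if (length(rows) == 0) {
      tibble(
        patient = character(), group = character(), gene = character(),
        mutation_id = character(), status = character()
      )
    } else {
      dplyr::bind_rows(rows)
    }
    df$cohort <- "simulated"
    as_cohort_mutation_table(
      df[, c("patient", "group", "cohort", "gene", "mutation_id", "status")],
      group_sizes = c(relapsed = n_relapsed, non_relapsed = n_nonrelapsed)
    )
  })
}
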