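test_that("identical parameters reproduce identical simulations", {
  p <- sim_params(seed = 123)
  a <- simulate_patient("common_progenitor", p)
  b <- simulate_patient("common_progenitor", p)
  expect_identical(a$readcounts, b$readcounts)
  expect_identical(a$trio$diagnosis, b$trio$diagnosis)
  tmpl <- random_str_templates(p)
  m1 <- simulate_str_mixture(tmpl$patient, tmpl$donor, 0.4, p)
  m2 <- simulate_str_mixture(tmpl$patient, tmpl$donor, 0.4, p)
  expect_identical(m1$relapse, m2$relapse)
  ge <- list(A = list(relapse_mut_prob = 0.4, nonrelapse_mut_prob = 0.1))
  expect_identical(simulate_cohort(10, 10, ge, p), simulate_cohort(10, 10, ge, p))
})

test_that("clone models enforce perfect phylogeny and fraction budgets", {
  bad_tree <- tibble::tibble(
    id = c("a", "b"), parent = c(NA, "a"),
    mutations = list(c("m1", "m2"), "m3"), # child lacks parent's mutations
    fraction_at_diagnosis = c(0.5, 0.5), fraction_at_relapse = c(0.5, 0.5)
  )
  expect_error(clone_model(bad_tree), "perfect phylogeny",
    class = "relapsekit_value_error")
  over <- tibble::tibble(
    id = c("a", "b"), parent = NA_character_,
    mutations = list("m1", "m2"),
    fraction_at_diagnosis = c(0.7, 0.7), fraction_at_relapse = c(0.1, 0.1)
  )
  expect_error(clone_model(over), "sum", class = "relapsekit_value_error")
})

test_that("generated mutation sets match the requested relapse pattern", {
  sm <- simulate_patient("second_malignancy", sim_params(seed = 2))
  diag_set <- sm$truth$mutation_id[sm$truth$cell_fraction_diagnosis > 0]
  rel_set <- sm$truth$mutation_id[sm$truth$cell_fraction_relapse > 0]
  expect_length(intersect(diag_set, rel_set), 0)

  sub <- simulate_patient("subclone_survival", sim_params(seed = 2))
  expect_true(all(sub$truth$status == "shared"))

  cp <- simulate_patient("common_progenitor", sim_params(seed = 2))
  expect_setequal(unique(cp$truth$status),
    c("shared", "diagnosis_specific", "relapse_specific"))
})

test_that("remission reads are zero without residual disease and scale with it", {
  sp <- simulate_patient("subclone_survival", sim_params(seed = 9))
  cr <- sp$readcounts[sp$readcounts$stage == "CR", ]
  cr_somatic <- cr[cr$gene %in% sp$truth$gene, ]
  expect_true(all(cr_somatic$var_reads == 0))

  model <- pattern_clone_model("subclone_survival", residual_cr_fraction = 0.2)
  sp2 <- simulate_patient("subclone_survival",
    sim_params(seed = 9, mean_depth = 2000, depth_dispersion = 0),
    model = model)
  cr2 <- sp2$readcounts[sp2$readcounts$stage == "CR", ]
  expect_true(any(cr2$var_reads > 0))
})

test_that("deep sequencing recovers the generating clone fractions", {
  # law of large numbers: at depth 1e5 the blast-adjusted VAF approaches
  # 100 * cell_fraction / 2 for every mutation
  sp <- simulate_patient("common_progenitor",
    sim_params(seed = 31, mean_depth = 1e5, depth_dispersion = 0,
      n_known_snp_contaminants = 0, n_donor_variants = 0))
  rc <- sp$readcounts[sp$readcounts$stage == "diagnosis", ]
  adj <- as.numeric(adjusted_vaf(rc$var_reads, rc$wt_reads, rc$blast_pct))
  truth <- sp$truth[match(rc$aa_change, sp$truth$mutation_id), ]
  expect_true(all(abs(adj - 100 * truth$cell_fraction_diagnosis / 2) <= 1))
})

test_that("cohort simulation matches its Bernoulli rates in the long run", {
  ge <- list(G1 = list(relapse_mut_prob = 0.46, nonrelapse_mut_prob = 0.17))
  fr_rel <- numeric(2000)
  fr_non <- numeric(2000)
  for (i in seq_len(2000)) {
    tab <- simulate_cohort(28, 30, ge, sim_params(seed = i))
    fr_rel[i] <- length(unique(tab$patient[tab$group == "relapsed"])) / 28
    fr_non[i] <- length(unique(tab$patient[tab$group == "non_relapsed"])) / 30
  }
  expect_lt(abs(mean(fr_rel) * 100 - 46), 2)
  expect_lt(abs(mean(fr_non) * 100 - 17), 2)
})

test_that("empty effect maps and zero probabilities yield empty tables", {
  ge <- list(G1 = list(relapse_mut_prob = 0, nonrelapse_mut_prob = 0))
  tab <- simulate_cohort(10, 10, ge, sim_params(seed = 1))
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "group_sizes"), c(relapsed = 10, non_relapsed = 10))
})

test_that("mixtures without specific alleles warn that loci are uninformative", {
  same <- make_profile("P", A = c("12" = 1000, "14" = 1000))
  expect_warning(
    simulate_str_mixture(same, same, 0.5, sim_params(seed = 1)),
    "uninformative"
  )
})
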