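test_that("the exact test matches enumeration and stats::fisher.test on small tables", {
  # exhaustive over all tables with total N <= 12
  for (a in 0:6) for (b in 0:(6 - a)) for (c in 0:6) for (d in 0:(6 - c)) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    got <- fisher_exact_two_sided(a, b, c, d)
    expect_equal(got, oracle_fisher_two_sided(a, b, c, d), tolerance = 1e-10,
      info = sprintf("(%d,%d,%d,%d)", a, b, c, d))
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(got, min(ft, 1), tolerance = 1e-9,
      info = sprintf("(%d,%d,%d,%d)", a, b, c, d))
  }
  # random larger tables with N <= 40
  withr::with_seed(99, {
    for (i in 1:100) {
      cells <- as.vector(stats::rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
      if (any(c(cells[1] + cells[2], cells[3] + cells[4],
        cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
      got <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got,
        oracle_fisher_two_sided(cells[1], cells[2], cells[3], cells[4]),
        tolerance = 1e-10)
    }
  })
})

test_that("exact-test edge cases and symmetries hold", {
  expect_warning(p0 <- fisher_exact_two_sided(0, 10, 0, 10), "zero margin")
  expect_equal(p0, 1)
  # fully separated 5/0 vs 0/5: two extreme tables of 252 equally likely
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / choose(10, 5),
    tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- sample(0:12, 4, replace = TRUE) + c(1, 0, 1, 0)
      p <- fisher_exact_two_sided(x[1], x[2], x[3], x[4])
      expect_gt(p, 0)
      expect_lte(p, 1)
      # simultaneous row and column swap leaves the table's p unchanged
      expect_equal(p, fisher_exact_two_sided(x[4], x[3], x[2], x[1]),
        tolerance = 1e-12)
    }
  })
  expect_lte(
    fisher_exact_two_sided(13, 15, 5, 25, midp = TRUE),
    fisher_exact_two_sided(13, 15, 5, 25)
  )
})

test_that("cohort fractions count each patient once and need explicit denominators", {
  tab <- as_cohort_mutation_table(
    tibble::tibble(
      patient = c("R1", "R1", "R2", "N1"),
      group = c("relapsed", "relapsed", "relapsed", "non_relapsed"),
      cohort = "x",
      gene = c("G1", "G2", "G1", "G3"),
      mutation_id = c("m1", "m2", "m3", "m4"),
      status = c("shared", "relapse_specific", "diagnosis_specific",
        "diagnosis_only_nonrelapsed")
    ),
    group_sizes = c(relapsed = 10, non_relapsed = 20)
  )
  # R1 has two mutations but counts once: 2/10
  expect_equal(mutated_patient_fraction(tab, "relapsed"), 20)
  expect_equal(mutated_patient_fraction(tab, "non_relapsed"), 5)
  expect_equal(mutated_patient_fraction(tab, "relapsed", group_size = 4), 50)
  no_meta <- as_cohort_mutation_table(tab, group_sizes = NULL)
  expect_error(mutated_patient_fraction(no_meta, "relapsed"),
    class = "relapsekit_value_error")
  expect_equal(gene_frequency(tab, "G1", 10), 20)
  expect_equal(gene_frequency(tab, "ABSENT", 10), 0)
  expect_equal(epigenetic_regulator_fraction(tab, character(), 10), 0)

  # brute-force oracle on a simulated table
  sim <- simulate_cohort(40, 40,
    list(A = list(relapse_mut_prob = 0.4, nonrelapse_mut_prob = 0.2),
      B = list(relapse_mut_prob = 0.3, nonrelapse_mut_prob = 0.1)),
    sim_params(seed = 5))
  want <- round_half_up(
    100 * length(unique(sim$patient[sim$group == "relapsed"])) / 40, 1)
  expect_equal(mutated_patient_fraction(sim, "relapsed"), want)
})

test_that("gene-level rule: at least two relapsed carriers, none non-relapsed, persisting at relapse", {
  base <- function(...) {
    df <- tibble::tibble(...)
    df$cohort <- "x"
    df$mutation_id <- paste0("m", seq_len(nrow(df)))
    as_cohort_mutation_table(df)
  }
  # boundary: exactly 2 relapsed carriers with shared status -> included
  tab <- base(
    patient = c("R1", "R2"), group = "relapsed",
    gene = "G1", status = "shared"
  )
  expect_equal(relapse_associated_genes(tab), "G1")
  # one non-relapsed carrier disqualifies
  tab2 <- base(
    patient = c("R1", "R2", "N1"),
    group = c("relapsed", "relapsed", "non_relapsed"),
    gene = "G1",
    status = c("shared", "shared", "diagnosis_only_nonrelapsed")
  )
  expect_length(relapse_associated_genes(tab2), 0)
  # two carriers whose mutations are all diagnosis-specific do not persist
  tab3 <- base(
    patient = c("R1", "R2"), group = "relapsed",
    gene = "G1", status = "diagnosis_specific"
  )
  expect_length(relapse_associated_genes(tab3), 0)
})

test_that("fraction operations ignore duplicate (patient, gene) records", {
  tab <- as_cohort_mutation_table(
    tibble::tibble(
      patient = "R1", group = "relapsed", cohort = "x", gene = "G1",
      mutation_id = c("m1", "m2", "m3"), status = "shared"
    ),
    group_sizes = c(relapsed = 2, non_relapsed = 0)
  )
  expect_equal(mutated_patient_fraction(tab, "relapsed"), 50)
  expect_equal(gene_frequency(tab, "G1", 2), 50)
  expect_equal(epigenetic_regulator_fraction(tab, "G1", 2), 50)
})
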