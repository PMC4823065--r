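# relapsekit

Genomic analysis of acute lymphoblastic leukemia (ALL) relapse after
allogeneic hematopoietic stem cell transplantation (allo-HSCT).

Adult Ph⁻ B-ALL patients who relapse after transplant carry leukemic cells
that survived both chemotherapy and the graft-versus-leukemia effect.
Analyzing how their mutation profile evolves from diagnosis (D) through
complete remission (CR) to post-transplant relapse (TR) — with the CR
sample as germline reference and the donor's DNA to rule out donor-derived
variants — identifies relapse-associated genes and the clonal route the
relapse took. relapsekit implements that pipeline for analysts working
from variant call tables, STR electropherogram peak tables and cohort
mutation tables:

* **Somatic candidate selection** (`call_somatic_candidates()`): call
  quality (mapping quality > 30, base quality > 15, variant reads > 3),
  known-SNP blacklist removal, tumor VAF ≥ 15% with ≥ 20× depth in either
  tumor sample, remission VAF < 0.5%, protein-altering effect, donor
  exclusion.
* **Clonal dynamics** (`adjusted_vaf()`, `classify_pattern()`,
  `clonal_report()`): blast-adjusted variant-in-tumor percentage
  `100·(v/(v+w))/(B/100)` for blast fraction `B`, per-mutation
  diagnosis/relapse status, and the patient-level clonal evolution pattern —
  *subclone survival* (all mutations shared), *common progenitor* (shared
  plus stage-specific mutations), or *second malignancy* (no shared
  mutations).
* **STR chimerism** (`estimate_chimerism()`): percentage of patient cells
  in a post-transplant sample, as the mean over informative STR loci of the
  CR-specific peak-height ratio `Σh_CR / (Σh_CR + Σh_donor)`.
* **Cohort statistics** (`fisher_exact_two_sided()`,
  `relapse_associated_genes()`, `mutated_patient_fraction()`): a
  self-contained two-sided Fisher exact test (minimum-likelihood
  convention) and the gene rule "mutated in ≥ 2 relapsed cases, in no
  non-relapsed case, persisting to or arising at relapse".
* **Synthetic cohorts** (`simulate_patient()`, `simulate_str_mixture()`,
  `simulate_cohort()`): clone trees under perfect phylogeny,
  blast-diluted binomial read counts, germline/donor contaminants and STR
  mixtures with known ground truth, so every stage runs and validates
  offline.

The published study's three printed tables ship as machine-readable
fixtures (`load_fixture("table1" | "table2" | "table3")`).

## Worked example

```r
library(relapsekit)

# Clonal evolution of the three whole-exome trio patients
t3 <- load_fixture("table3")
clonal_report(t3)$patterns
#> # A tibble: 3 × 5
#>   patient n_shared n_diagnosis_specific n_relapse_specific pattern
#>   <chr>      <int>                <int>              <int> <chr>
#> 1 ALL001         8                    0                  0 subclone_survival
#> 2 ALL002         2                    5                  2 common_progenitor
#> 3 ALL003         0                    4                  4 second_malignancy

# Blast-adjusted VAF for one mutation (OXTR; diagnosis, relapse, CR)
oxtr <- t3[t3$gene == "OXTR", ]
adjusted_vaf(oxtr$var_reads, oxtr$wt_reads, oxtr$blast_pct)
#> [1] 62.3 53.5  0.0
```

ALL001's OXTR mutation sits in 62.3% of tumor cells at diagnosis and 53.5%
at relapse (consistent with a heterozygous mutation in most tumor cells),
and is absent in remission; every ALL001 mutation is shared between
diagnosis and relapse, so its relapse clone is a surviving subclone of the
diagnosed tumor. ALL003's relapse shares nothing with its diagnosis — a
second malignancy.

```r
# Cohort level: relapse-associated genes and mutation enrichment
t2 <- load_fixture("table2")
relapse_associated_genes(t2)
#> [1] "CREBBP" "KDM6A"  "KRAS"   "NR3C1"  "PTPN21" "SETD2"  "USP54"
fisher_exact_two_sided(13, 15, 5, 25)   # mutated patients, relapsed vs not
#> [1] 0.02254615

# Chimerism: simulate a 30% patient / 70% donor mixture and recover it
p <- sim_params(seed = 7, str_noise_cv = 0.1)
tmpl <- random_str_templates(p)
mix <- simulate_str_mixture(tmpl$patient, tmpl$donor, patient_fraction = 0.3, p)
est <- estimate_chimerism(mix$cr, mix$donor, mix$relapse)
sprintf("%.1f%% patient cells over %d informative loci", est$patient_pct, est$n_loci)
#> [1] "30.1% patient cells over 15 informative loci"
```

The p-value of 0.023 marks the enrichment of somatic mutations in relapsed
(13/28) versus non-relapsed (5/30) patients as significant; the seven genes
are those recurrently mutated in relapsed cases only.

See `vignettes/relapse-genomics-methods.Rmd` for the models, assumptions,
parameter choices and known limitations.

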