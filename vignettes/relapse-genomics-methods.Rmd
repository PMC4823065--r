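---
title: "Methods: somatic filtering, clonal evolution and chimerism after allo-HSCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering, clonal evolution and chimerism after allo-HSCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsekit)
```

## The problem

Relapse is the leading cause of death after allogeneic hematopoietic stem
cell transplantation (allo-HSCT) in adult Philadelphia-chromosome-negative
B-cell acute lymphoblastic leukemia (Ph− B-ALL). relapsekit implements the
computational core of a longitudinal relapse-genomics analysis of matched
samples taken at diagnosis (D), complete remission (CR, after chemotherapy
but before transplant) and relapse after transplant (TR), together with the
stem cell donor's DNA:

1. **Candidate somatic mutation selection** from per-sample variant call
   tables, using the CR sample as the germline reference and the donor
   sample to exclude donor-derived variants.
2. **Blast-adjusted variant allele frequencies** and classification of each
   patient's **clonal evolution pattern** at relapse.
3. **STR peak-height chimerism estimation** — the percentage of patient
   (vs donor) cells in a post-transplant relapse sample.
4. **Cohort enrichment statistics** — mutated-patient fractions, per-gene
   recurrence, a relapse-association gene rule, and a self-contained
   two-sided Fisher exact test.
5. A **synthetic cohort generator** with known ground truth so that every
   stage can be exercised and validated offline.

The package ships machine-readable transcriptions of the study's three
printed tables (`load_fixture()`), which double as worked examples and as
the reference surface the test suite checks against.

## Candidate somatic mutation selection

Upstream read processing (alignment, duplicate removal, recalibration,
variant calling, annotation) is out of scope: the package consumes call
tables. The selection rule re-applied here, with all thresholds exposed via
`filter_thresholds()`, is:

* **call quality** (strict inequalities): mapping quality > 30, base
  quality > 15, variant reads > 3 — a call with exactly 3 supporting reads
  is discarded;
* **known variants**: exact (chrom, pos, ref, alt) matches against a
  user-supplied blacklist (e.g. common database SNPs) are removed; no
  database is downloaded;
* **tumor evidence**: VAF ≥ 15% with depth ≥ 20× — both in the *same*
  tumor sample — in the diagnosis **or** relapse sample. We read "in either
  tumor sample" literally as at-least-one; `tumor_rule = "both"` switches to
  the stricter conjunction;
* **remission evidence**: CR VAF < 0.5%. A site absent from the CR table,
  or covered by zero reads (warned about), counts as VAF 0 — remission
  rows with zero variant reads are treated as absence;
* **protein-altering effect**: nonsynonymous, frameshift, stopgain,
  in-frame indel or splice-site; synonymous and unclassified calls are
  dropped;
* **donor exclusion**: any donor-sample presence (variant reads > 0 after
  the quality pre-filter) excludes the variant as donor-derived. No VAF
  threshold is applied because presence in donor germline DNA is
  disqualifying regardless of level; excluded variants are reported under
  the `"donor_origin"` attribute rather than silently dropped.

The implementation is deliberately mirrored by an independent brute-force
predicate in the test suite, and the two are required to agree exactly on
randomized trios whose read counts, qualities and blacklist membership
straddle every decision boundary.

## Blast-adjusted VAF and clonal evolution patterns

Marrow samples are a mixture of leukemic blasts and normal cells. With
blast percentage $B$ and raw variant allele frequency
$\hat v = \frac{\text{var}}{\text{var}+\text{wt}}$, the percentage of tumor
cells carrying the variant is estimated as

$$\%\text{Variant in tumor} = 100\cdot\frac{\hat v}{B/100},$$

reported to one decimal with ties rounded half away from zero
(`round_half_up()`), matching the presentation of the source table; CR rows
have no blast estimate and are reported as raw VAF. Values above 100 are
returned as computed with a `super_clonal` flag — they indicate loss of
heterozygosity, copy-number change or an underestimated blast fraction, and
deciding among those is beyond what read counts alone support. Recomputing
the packaged read-count table reproduces the printed column exactly for 73
of 75 cells; the two discordant cells are stored as printed and flagged
`formula_discordant` rather than corrected.

Under the diploid heterozygous assumption, a mutation carried by a fraction
$f$ of tumor cells has expected adjusted VAF $100 \cdot f/2$; the study's
reading of 40–50% adjusted VAF as "virtually all tumor cells" rests on
exactly this factor of 2, and the simulator makes the same assumption
(with a per-clone `copy_multiplier` escape hatch, default 1).

Pattern classification uses mutation presence/absence only. With $S$
shared, $D$ diagnosis-specific and $R$ relapse-specific mutations:

| condition | pattern |
|---|---|
| $S = 0$ | second malignancy (distinct mutation set) |
| $S > 0$, $D = R = 0$ | subclone survival (relapse clone pre-existed) |
| $S > 0$, $D > 0$ or $R > 0$ | common progenitor (divergent evolution) |

VAF magnitudes do not change the label; they feed the separate
`vaf_shift()` trend call (rising/stable/falling), for which we chose a
minimum shift of 5 percentage points — the source describes "significant"
increases of roughly 10–20 points but states no threshold, and 5 points
sits comfortably above binomial counting noise at ≥ 20× depth while
remaining sensitive to the reported shifts. Phylogenetic reconstruction
and VAF-clustering of clones are out of scope.

## STR chimerism

After engraftment, a relapse marrow sample is a patient/donor cell mixture.
Fifteen polymorphic STR loci (the Identifiler panel) are genotyped in the
CR sample (pure patient), the donor sample, and the relapse sample. A locus
is *informative* when at least one CR-specific and one donor-specific
allele are both detected in the relapse electropherogram **and** some such
pair differs by at most one repeat unit ("less than two"); size-matched
alleles amplify with comparable efficiency, keeping the peak-height ratio
quantitative. We read the pairing rule as a qualification test for the
locus, while the ratio itself sums over *all* detected specific alleles:

$$r_\ell = \frac{\sum_{a \in \text{CR-specific}} h_a}
               {\sum_{a \in \text{CR-specific}} h_a +
                \sum_{a \in \text{donor-specific}} h_a},$$

and the patient-cell percentage is $100$ × the unweighted mean of $r_\ell$
over informative loci (the source says "average ratio values", so no
height weighting). Peak detection needs a threshold the protocol does not
state; we default to 50 RFU, a common analytical threshold for capillary
electrophoresis, configurable in `informative_loci()`.

No worked numeric example of this estimator is printed in the source, so
validation is simulation-based: noise-free mixtures must be recovered
exactly (peak height proportional to cell fraction by construction), the
patient/donor-swap symmetry $\hat p \mapsto 100-\hat p$ must hold, and
under 10% multiplicative lognormal peak noise the estimate must fall within
3 percentage points of truth in ≥ 95% of 200 seeded replicates.

## Cohort statistics

`fisher_exact_two_sided()` is implemented in the package (log-factorial
hypergeometric probabilities; two-sided p as the sum over all tables with
the observed margins whose probability does not exceed the observed
table's, with a $10^{-7}$ relative tolerance against floating-point ties —
the minimum-likelihood convention of standard statistics software, needed
to reproduce the published p = 0.023 for the 13/28 vs 5/30 comparison).
A mid-p variant is available behind a flag. The test suite checks the
implementation against a direct `dhyper` enumeration and against
`stats::fisher.test` over exhaustive small tables; those routines are
oracles only, never the implementation.

Patient-level fractions count each patient once regardless of how many
mutations they carry, and denominators (28 extension relapsed, 30
non-relapsed, 31 relapsed overall, 13 mutated relapsed) are explicit
metadata — patients without mutations have no table rows, so denominators
can never be inferred from the records. A gene is *relapse-associated* when
it is mutated in ≥ 2 relapsed cases, in 0 non-relapsed cases, and at least
one relapsed patient's mutation persists to or arises at relapse (status
`shared` or `relapse_specific`); applied to the packaged cohort table this
yields exactly the published seven genes (SETD2, CREBBP, KDM6A, NR3C1,
KRAS, PTPN21, USP54). One printed figure — 16.7% mutated among non-relapsed
patients, i.e. 5/30 — is not reproducible from the packaged table, which
names only four non-relapsed carriers; the fifth is not identifiable from
the printed records, so the 2×2 test takes its counts (13/15/5/25) as
direct inputs rather than deriving the non-relapsed count from the table.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are fixed study
conditions, not tuning knobs:

* **depth**: negative binomial with mean 100 (the study's ~106× mean exome
  coverage) and dispersion 0.15, giving per-site depths of roughly 15–170
  reads — the spread of the printed read-count table; dispersion 0
  degenerates to fixed depth;
* **read counts**: var_reads ~ Binomial(depth, $B \cdot f/2$) for a
  mutation in cell fraction $f$ at blast fraction $B$ (heterozygous
  diploid); CR counts use residual fraction × diagnosis cell fraction / 2,
  default residual 0 (minimal residual disease < 10⁻⁴ in the study design);
* **clone trees**: perfect phylogeny (child mutation sets are supersets of
  parent's), per-stage clone fractions summing to ≤ 1. Default pattern
  models: subclone survival = founder + subclone at fractions 0.8/0.2
  flipping to 0.2/0.8; common progenitor = shared trunk plus a diagnosis
  clone and a relapse clone each adding private mutations; second
  malignancy = two unrelated clones with disjoint sets;
* **contaminants**: 20 germline common SNPs (VAF ½ in all patient samples;
  returned as the blacklist) and 5 donor-origin variants (VAF ½ in relapse
  and donor samples only — donor cells populate the post-transplant
  marrow, while the CR sample predates the transplant), so the somatic
  filter's removal paths are exercised;
* **STR mixtures**: relapse peak height = template height × owning
  population fraction, times lognormal noise with cv 0.1 (unit mean);
  template heights are equal across alleles by default, so height is
  exactly proportional to cell fraction and noise-free recovery is exact; a
  `height_jitter` argument introduces unequal amplification efficiencies
  for stress testing. Stutter (a peak one repeat unit below, default off)
  is available for robustness checks only;
* **determinism**: every simulator runs under `withr::with_seed()` on the
  seed in `sim_params()`, so identical parameters give identical output
  without touching the caller's RNG state.

What the generator does *not* emulate: sequencing error (no false-positive
reads, so simulated presence/absence is cleaner than real calls),
copy-number change and LOH, indel alignment artifacts, stutter
deconvolution, and related (rather than unrelated) donor STR genotypes.
Recovery results on simulated data therefore bound what the estimators can
do when their model assumptions hold; they do not certify performance on
real electropherograms or noisy call sets.

Presence calling on simulated read counts (for pattern recovery) uses
variant reads ≥ 3 and VAF ≥ 2% — at depth 100 and cell fraction ≥ 0.2 with
90% blasts, the per-mutation miss probability is below 1%, which keeps the
patient-level pattern recovery above the 95% requirement while the 2% VAF
floor guards against low-level noise once an error model is added.

## Problem sizes and numerical choices

The validation suite runs at desk scale: exhaustive Fisher cross-checks on
all 2×2 tables of total ≤ 12 plus 100 random tables of total ≤ 40;
200 chimerism replicates and 210 pattern-recovery trios; 2000 cohort
Bernoulli replicates; oracle equivalence on 50–100-variant trios. The whole
suite completes in about a minute on one CPU.

Rounding to one decimal uses half-away-from-zero with an epsilon guard of
`sqrt(.Machine$double.eps)` against binary representation error (e.g.
62.25 stored fractionally below the tie). Internal computations keep full
precision; rounding is applied only at the reporting surface.

## Known limitations

* The donor-exclusion rule is presence-based; a contaminating tumor read in
  the donor sample would wrongly exclude a true somatic variant. A VAF
  threshold could be exposed, but the source supplies no value.
* `classify_pattern` trusts its input statuses; with shallow sequencing the
  presence calls feeding it dominate accuracy.
* Chimerism assumes peak height proportional to template amount within a
  locus; severe amplification bias between alleles more than one repeat
  apart is mitigated by the pairing rule but not modeled away.
* The self-implemented Fisher test handles the 2×2 case only, matching its
  use here.
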