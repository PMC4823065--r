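# Peaks at or above this height (RFU) count as detected; the published
# protocol states no analytical threshold, so it is exposed as an argument.
DEFAULT_MIN_PEAK_HEIGHT <- 50

profile_peaks <- function(profile, locus, min_height = 0) {
  p <- profile[profile$locus == locus & profile$height >= min_height, ]
  setNames(p$height, p$allele_repeats)
}

#' Sample-specific STR alleles at one locus
#'
#' @param cr,donor `str_profile` tibbles for the patient's complete-remission
#'   sample (pure patient) and the donor sample.
#' @param locus Locus name, present in both profiles.
#' @return List with `cr_specific` and `donor_specific`: integer vectors of
#'   repeat numbers seen in one profile but not the other.  Both empty means
#'   the locus cannot be informative.
#' @export
specific_alleles <- function(cr, donor, locus) {
  if (!locus %in% cr$locus || !locus %in% donor$locus) {
    abort(sprintf("locus '%s' missing from a profile", locus),
      class = "relapsekit_value_error")
  }
  cr_alleles <- unique(cr$allele_repeats[cr$locus == locus])
  donor_alleles <- unique(donor$allele_repeats[donor$locus == locus])
  list(
    cr_specific = sort(setdiff(cr_alleles, donor_alleles)),
    donor_specific = sort(setdiff(donor_alleles, cr_alleles))
  )
}

#' Identify informative STR loci for chimerism estimation
#'
#' A locus is informative when at least one CR-specific (patient) allele and
#' one donor-specific allele are both detected in the relapse sample, and at
#' least one such pair differs by no more than `max_repeat_diff` repeat units
#' (the published rule: less than two units, so a difference of at most one)
#' — size-matched alleles amplify with comparable efficiency, keeping the
#' peak-height ratio quantitative.  The per-locus ratio sums over all
#' specific alleles detected in the relapse sample, not only the qualifying
#' pair.
#'
#' @inheritParams specific_alleles
#' @param relapse `str_profile` tibble of the post-transplant relapse sample
#'   (a patient/donor cell mixture).
#' @param max_repeat_diff Maximum repeat-unit difference between a CR- and a
#'   donor-specific allele for the locus to qualify (default 1).
#' @param min_peak_height Detection threshold in RFU (default 50): relapse
#'   peaks below it are treated as absent.
#' @return Tibble with one row per informative locus: `locus`,
#'   `cr_specific` and `donor_specific` (list-columns of repeat numbers
#'   detected in the relapse sample), `cr_height`, `donor_height`, `ratio`.
#'   Zero rows when no locus qualifies.
#' @export
informative_loci <- function(cr, donor, relapse, max_repeat_diff = 1,
                             min_peak_height = DEFAULT_MIN_PEAK_HEIGHT) {
  loci <- intersect(intersect(unique(cr$locus), unique(donor$locus)),
    unique(relapse$locus))
  rows <- list()
  for (locus in loci) {
    sp <- specific_alleles(cr, donor, locus)
    rel_peaks <- profile_peaks(relapse, locus, min_peak_height)
    rel_alleles <- as.integer(names(rel_peaks))
    cr_seen <- intersect(sp$cr_specific, rel_alleles)
    donor_seen <- intersect(sp$donor_specific, rel_alleles)
    if (length(cr_seen) == 0 || length(donor_seen) == 0) next
    diffs <- abs(outer(cr_seen, donor_seen, "-"))
    if (min(diffs) > max_repeat_diff) next
    cr_height <- sum(rel_peaks[as.character(cr_seen)])
    donor_height <- sum(rel_peaks[as.character(donor_seen)])
    if (cr_height + donor_height <= 0) {
      abort(sprintf("locus '%s': zero total specific-peak height", locus),
        class = "relapsekit_value_error")
    }
    rows[[locus]] <- tibble(
      locus = locus,
      cr_specific = list(cr_seen),
      donor_specific = list(donor_seen),
      cr_height = cr_height,
      donor_height = donor_height,
      ratio = cr_height / (cr_height + donor_height)
    )
  }
  if (length(rows) == 0) {
    return(tibble(
      locus = character(), cr_specific = list(), donor_specific = list(),
      cr_height = numeric(), donor_height = numeric(), ratio = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Patient-specific peak-height ratio at one informative locus
#'
#' Ratio of the summed relapse peak heights of the CR-specific alleles to
#' the summed heights of both the CR- and donor-specific alleles.
#'
#' @param cr_specific,donor_specific Integer vectors of specific allele
#'   repeat numbers detected in the relapse sample (both non-empty).
#' @param relapse `str_profile` tibble of the relapse sample.
#' @param locus Locus name.
#' @return Fraction in \[0, 1\].
#' @export
locus_ratio <- function(cr_specific, donor_specific, relapse, locus) {
  if (length(cr_specific) == 0 || length(donor_specific) == 0) {
    abort("both specific-allele sets must be non-empty (informative locus)",
      class = "relapsekit_value_error")
  }
  peaks <- profile_peaks(relapse, locus)
  ch <- sum(peaks[as.character(cr_specific)], na.rm = TRUE)
  dh <- sum(peaks[as.character(donor_specific)], na.rm = TRUE)
  if (ch + dh <= 0) {
    abort(sprintf("locus '%s': zero total specific-peak height", locus),
      class = "relapsekit_value_error")
  }
  ch / (ch + dh)
}

#' Estimate the percentage of patient cells in a relapse sample
#'
#' Unweighted mean of the per-locus CR-specific peak-height ratios over all
#' informative loci, expressed as a percentage.
#'
#' @param loci Informative-locus table from [informative_loci()].
#' @return Object of class `chimerism_estimate`: a list with `patient_pct`,
#'   `n_loci` and the per-locus table `loci`.
#' @export
estimate_patient_fraction <- function(loci) {
  if (nrow(loci) == 0) {
    abort("no informative loci", class = "relapsekit_value_error")
  }
  structure(
    list(
      patient_pct = 100 * mean(loci$ratio),
      n_loci = nrow(loci),
      loci = loci
    ),
    class = "chimerism_estimate"
  )
}

#' @export
print.chimerism_estimate <- function(x, ...) {
  cat(sprintf("Patient cells in relapse sample: %.1f%% (%d informative loci)\n",
    x$patient_pct, x$n_loci))
  for (i in seq_len(nrow(x$loci))) {
    cat(sprintf("  %-10s ratio %.3f\n", x$loci$locus[i], x$loci$ratio[i]))
  }
  invisible(x)
}

#' One-call chimerism estimation from three STR profiles
#'
#' Convenience wrapper running [informative_loci()] then
#' [estimate_patient_fraction()].
#'
#' @inheritParams informative_loci
#' @return A `chimerism_estimate` (see [estimate_patient_fraction()]).
#' @export
estimate_chimerism <- function(cr, donor, relapse, max_repeat_diff = 1,
                               min_peak_height = DEFAULT_MIN_PEAK_HEIGHT) {
  estimate_patient_fraction(
    informative_loci(cr, donor, relapse, max_repeat_diff, min_peak_height)
  )
}
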