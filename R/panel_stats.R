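# Cutoff sensitivity sweep, per-analyzer allergen positivity profiles, and
# multi-positive-per-patient summaries.

#' Recompute agreement statistics across several cutoffs
#'
#' Applies each cutoff to the same stored class-level pairs (one dataset
#' pass, no re-dichotomized intermediates), so agreement and concordant
#' positive rate across cutoffs are directly comparable. The concordant
#' positive rate is non-increasing in the cutoff for fixed pairs; total
#' agreement may move either way.
#'
#' @param pair_set a [build_pair_set()] result.
#' @param cutoffs integer vector of cutoffs, each in 1..6; default `1:3`,
#'   the conventional sensitivity range around the class-2 convention.
#' @return long data.frame with columns `cutoff`, `allergen`, `n`,
#'   `agreement_pct`, `concordant_positive_pct` (full precision).
#' @export
cutoff_sweep <- function(pair_set, cutoffs = 1:3) {
  stopifnot(inherits(pair_set, "pair_set"), length(cutoffs) >= 1)
  cutoffs <- vapply(cutoffs, check_cutoff, integer(1))
  allergens <- sort(unique(pair_set$pairs$allergen))
  rows <- lapply(cutoffs, function(t) {
    do.call(rbind, lapply(allergens, function(al) {
      tab <- tabulate_pairs(pairs_for_allergen(pair_set, al), t)
      data.frame(cutoff = t, allergen = al, n = tab$N,
                 agreement_pct = total_agreement(tab),
                 concordant_positive_pct = concordant_positive_rate(tab))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positivity profile of one analyzer
#'
#' For a single analyzer and panel, counts patients with class at or above
#' the cutoff per allergen. This is how analyzer-specific allergens (present
#' on no other panel, hence with no agreement statistics) are characterized.
#'
#' @param dataset a [mast_dataset()].
#' @param analyzer analyzer identifier.
#' @param panel `"food"` or `"inhalant"`.
#' @param cutoff minimal class counted positive; profiles of
#'   analyzer-specific allergens conventionally use cutoff 1.
#' @return object of class `positivity_profile`: data.frame with `allergen`,
#'   `n_positive`, `rate_pct`, plus attribute `n_patients` (distinct
#'   patients with any record for this analyzer and panel).
#' @export
positivity_profile <- function(dataset, analyzer, panel, cutoff = 1L) {
  stopifnot(inherits(dataset, "mast_dataset"))
  panel <- match.arg(panel, c("food", "inhalant"))
  cutoff <- check_cutoff(cutoff)
  sub <- dataset[dataset$analyzer == analyzer & dataset$panel == panel, ,
                 drop = FALSE]
  if (nrow(sub) == 0) {
    mast_abort(sprintf("no records for analyzer '%s' on the %s panel",
                       analyzer, panel), "mast_empty_comparison")
  }
  n_patients <- length(unique(sub$patient_id))
  pos <- sub[sub$class >= cutoff, , drop = FALSE]
  allergens <- sort(unique(sub$allergen))
  counts <- vapply(allergens, function(al) {
    length(unique(pos$patient_id[pos$allergen == al]))
  }, integer(1))
  out <- data.frame(allergen = allergens, n_positive = unname(counts),
                    rate_pct = unname(counts) * 100 / n_patients)
  rownames(out) <- NULL
  structure(out, n_patients = n_patients, analyzer = analyzer, panel = panel,
            cutoff = cutoff, class = c("positivity_profile", "data.frame"))
}

#' Multi-positive results per patient
#'
#' Counts, for one analyzer and panel, how many allergens each patient is
#' positive for at the cutoff, the number of patients with two or more
#' positive allergens (a proxy for cross-reactivity burden), and the
#' maximum per-patient count.
#'
#' @inheritParams positivity_profile
#' @param cutoff minimal class counted positive; default 2.
#' @return list with `per_patient` (data.frame `patient_id`, `n_positive`),
#'   `patients_with_multiple`, `max_positive_allergens`, `n_patients`,
#'   `analyzer`, `panel`, `cutoff`.
#' @export
multi_positive_summary <- function(dataset, analyzer, panel, cutoff = 2L) {
  stopifnot(inherits(dataset, "mast_dataset"))
  panel <- match.arg(panel, c("food", "inhalant"))
  cutoff <- check_cutoff(cutoff)
  sub <- dataset[dataset$analyzer == analyzer & dataset$panel == panel, ,
                 drop = FALSE]
  if (nrow(sub) == 0) {
    mast_abort(sprintf("no records for analyzer '%s' on the %s panel",
                       analyzer, panel), "mast_empty_comparison")
  }
  patients <- sort(unique(sub$patient_id))
  counts <- vapply(patients, function(p) {
    sum(sub$class[sub$patient_id == p] >= cutoff)
  }, integer(1))
  per_patient <- data.frame(patient_id = patients, n_positive = unname(counts))
  rownames(per_patient) <- NULL
  list(per_patient = per_patient,
       patients_with_multiple = sum(counts >= 2),
       max_positive_allergens = if (length(counts)) max(counts) else 0L,
       n_patients = length(patients),
       analyzer = analyzer, panel = panel, cutoff = cutoff)
}
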