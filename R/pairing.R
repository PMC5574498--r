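# Matched-pair construction: the unit of analysis is one (patient, allergen)
# with readings from both analyzers under comparison. Readings lacking a
# counterpart are excluded and logged, mirroring the matched-allergen
# same-sample design of inter-analyzer comparisons.

#' Build the matched-pair set for a two-analyzer comparison
#'
#' For every (patient, allergen) carrying a reading from both analyzers on
#' the given panel, emits one matched pair. Readings present on one side
#' only are dropped and recorded in the drop log (the audit trail of the
#' exclusion rule).
#'
#' @param dataset a [mast_dataset()].
#' @param analyzer_a,analyzer_b analyzer identifiers; `analyzer_a` is the
#'   "A" side of all downstream statistics.
#' @param panel `"food"` or `"inhalant"`.
#' @return object of class `pair_set`: list with `analyzer_a`, `analyzer_b`,
#'   `panel`, `pairs` (data.frame `patient_id`, `allergen`, `class_a`,
#'   `class_b`), `dropped` (data.frame `patient_id`, `allergen`,
#'   `present_side`), and `n_patients` (distinct patients among pairs).
#' @export
build_pair_set <- function(dataset, analyzer_a, analyzer_b, panel) {
  stopifnot(inherits(dataset, "mast_dataset"))
  panel <- match.arg(panel, c("food", "inhalant"))
  if (analyzer_a == analyzer_b) {
    mast_abort("analyzer_a and analyzer_b must differ", "mast_invalid_comparison")
  }
  for (an in c(analyzer_a, analyzer_b)) {
    if (!an %in% dataset$analyzer) {
      mast_abort(sprintf("analyzer '%s' has no records in dataset", an),
                 "mast_empty_comparison")
    }
  }
  sub <- dataset[dataset$panel == panel &
                   dataset$analyzer %in% c(analyzer_a, analyzer_b), , drop = FALSE]
  a <- sub[sub$analyzer == analyzer_a, c("patient_id", "allergen", "class")]
  b <- sub[sub$analyzer == analyzer_b, c("patient_id", "allergen", "class")]
  names(a)[3] <- "class_a"
  names(b)[3] <- "class_b"
  pairs <- merge(a, b, by = c("patient_id", "allergen"), sort = TRUE)
  only_a <- merge(a, b[c("patient_id", "allergen")], by = c("patient_id", "allergen"))
  drop_a <- a[!paste(a$patient_id, a$allergen) %in%
                paste(only_a$patient_id, only_a$allergen), 1:2, drop = FALSE]
  drop_b <- b[!paste(b$patient_id, b$allergen) %in%
                paste(pairs$patient_id, pairs$allergen), 1:2, drop = FALSE]
  dropped <- rbind(
    if (nrow(drop_a) > 0) cbind(drop_a, present_side = analyzer_a),
    if (nrow(drop_b) > 0) cbind(drop_b, present_side = analyzer_b)
  )
  if (is.null(dropped)) {
    dropped <- data.frame(patient_id = character(0), allergen = character(0),
                          present_side = character(0))
  }
  rownames(pairs) <- rownames(dropped) <- NULL
  if (nrow(pairs) == 0) {
    mast_abort(sprintf("no matched pairs between '%s' and '%s' on the %s panel",
                       analyzer_a, analyzer_b, panel),
               "mast_empty_comparison")
  }
  structure(
    list(analyzer_a = analyzer_a, analyzer_b = analyzer_b, panel = panel,
         pairs = pairs, dropped = dropped,
         n_patients = length(unique(pairs$patient_id))),
    class = "pair_set"
  )
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %s vs %s, %s panel: %d pairs, %d patients, %d allergens (%d dropped one-sided)\n",
              x$analyzer_a, x$analyzer_b, x$panel, nrow(x$pairs), x$n_patients,
              length(unique(x$pairs$allergen)), nrow(x$dropped)))
  invisible(x)
}

#' Matched pairs for one allergen
#'
#' @param pair_set a [build_pair_set()] result.
#' @param allergen canonical allergen name.
#' @return data.frame of matched pairs (possibly zero rows); per-allergen N
#'   may differ across allergens when sample volume limited testing.
#' @export
pairs_for_allergen <- function(pair_set, allergen) {
  stopifnot(inherits(pair_set, "pair_set"))
  out <- pair_set$pairs[pair_set$pairs$allergen == allergen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the one-sided-reading drop log as TSV
#'
#' @param pair_set a [build_pair_set()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(pair_set, path) {
  stopifnot(inherits(pair_set, "pair_set"))
  utils::write.table(pair_set$dropped, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
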