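# Positive propensity: a signed, directional discordance statistic.
#
# For a comparison of analyzer A against analyzer B on one allergen,
# propensity = (n_pn - n_np) * 100 / N: the excess of A-only positives over
# B-only positives as a percentage of all pairs. A value >= 10% is read as a
# positive propensity of A (A systematically calls this allergen positive
# where B does not); values below 5% are reported as NS (not significant).
# Values in between are listed without the >= 10% interpretation.

#' Propensity reporting thresholds
#'
#' @param presence percent at or above which the excess is flagged as a
#'   positive propensity (default 10).
#' @param ns percent below which the excess is reported as NS, not
#'   significant (default 5). Must satisfy `0 <= ns <= presence <= 100`.
#' @return object of class `propensity_thresholds`.
#' @export
propensity_thresholds <- function(presence = 10, ns = 5) {
  if (!(ns >= 0 && ns <= presence && presence <= 100)) {
    mast_abort("need 0 <= ns <= presence <= 100", "mast_invalid_thresholds")
  }
  structure(list(presence = presence, ns = ns), class = "propensity_thresholds")
}

#' Signed positive-propensity statistic
#'
#' `(n_pn - n_np) * 100 / N`. Positive values favor analyzer A (more A-only
#' positives), negative values favor analyzer B. Antisymmetric under
#' swapping the analyzers.
#'
#' @param table a [paired_table()].
#' @return signed percentage in `[-100, 100]`.
#' @export
positive_propensity <- function(table) {
  check_table(table)
  (table$n_pn - table$n_np) * 100 / table$N
}

PROPENSITY_LEVELS <- c("NS", "reported", "positive_propensity")

#' Categorize a signed propensity value for each analyzer
#'
#' The side with the positive excess is `positive_propensity` when the
#' magnitude reaches the presence threshold, `reported` when it is at least
#' the NS threshold but below presence, `NS` otherwise. The opposite side is
#' always `NS`.
#'
#' @param value signed propensity percent (A-positive convention).
#' @param thresholds a [propensity_thresholds()].
#' @return named character vector `c(category_a, category_b)` with levels
#'   `"NS"`, `"reported"`, `"positive_propensity"`.
#' @export
classify_propensity <- function(value, thresholds = propensity_thresholds()) {
  stopifnot(inherits(thresholds, "propensity_thresholds"), length(value) == 1,
            !is.na(value))
  one_side <- function(mag) {
    if (mag >= thresholds$presence) "positive_propensity"
    else if (mag >= thresholds$ns) "reported"
    else "NS"
  }
  c(category_a = if (value > 0) one_side(value) else "NS",
    category_b = if (value < 0) one_side(-value) else "NS")
}

#' Per-allergen propensity report for a comparison
#'
#' One row per allergen on which at least one analyzer's excess is at least
#' the NS threshold; allergens NS on both sides are omitted, mirroring
#' published propensity tables that list flagged allergens only. The signed
#' statistic is presented as two one-sided columns (`prop_a_pct`,
#' `prop_b_pct`), of which at most one is positive.
#'
#' @param pair_set a [build_pair_set()] result.
#' @param cutoff minimal class counted positive.
#' @param thresholds a [propensity_thresholds()].
#' @return data.frame with columns `allergen`, `n`, `prop_a_pct`,
#'   `prop_b_pct`, `category_a`, `category_b`.
#' @export
propensity_report <- function(pair_set, cutoff = 2L,
                              thresholds = propensity_thresholds()) {
  stopifnot(inherits(pair_set, "pair_set"))
  allergens <- sort(unique(pair_set$pairs$allergen))
  rows <- lapply(allergens, function(al) {
    tab <- tabulate_pairs(pairs_for_allergen(pair_set, al), cutoff)
    v <- positive_propensity(tab)
    cats <- classify_propensity(v, thresholds)
    data.frame(allergen = al, n = tab$N,
               prop_a_pct = max(v, 0), prop_b_pct = max(-v, 0),
               category_a = cats[["category_a"]],
               category_b = cats[["category_b"]])
  })
  out <- do.call(rbind, rows)
  out <- out[out$category_a != "NS" | out$category_b != "NS", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format a propensity report for display
#'
#' Percent columns at 1 dp, half away from zero; sides categorized NS print
#' as `"NS"`, mirroring the two-sided column layout of published tables.
#'
#' @param report data.frame from [propensity_report()].
#' @return data.frame of character columns.
#' @export
format_propensity_report <- function(report) {
  fmt_side <- function(v, cat) ifelse(cat == "NS", "NS",
                                      sprintf("%.1f", round_half_up(v, 1)))
  data.frame(
    allergen = report$allergen, n = report$n,
    prop_a_pct = fmt_side(report$prop_a_pct, report$category_a),
    prop_b_pct = fmt_side(report$prop_b_pct, report$category_b),
    category_a = report$category_a, category_b = report$category_b
  )
}
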