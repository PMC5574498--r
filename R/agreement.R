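# Dichotomization, 2x2 tabulation, total agreement percentage, concordant
# positive rate, and Cohen's kappa with its large-sample (delta-method)
# standard error and normal-approximation confidence interval.
#
# Kappa is UNDEFINED (returned as NA) exactly when the chance-expected
# agreement p_e equals 1, i.e. when every pair is concordant-positive or
# every pair is concordant-negative; this is a first-class result state,
# matching the "NA" cells seen in published comparison tables, never a
# silent zero.

#' Dichotomize a class level at a cutoff
#'
#' A semi-quantitative class 0-6 counts as positive when it is at or above
#' the cutoff class. Class 2 is the conventional cutoff (class 1 is often
#' read as insufficient clinical significance); cutoffs 1 and 3 are used in
#' sensitivity sweeps.
#'
#' @param class_level integer vector of class levels 0-6.
#' @param cutoff minimal class counted positive, integer in 1-6.
#' @return logical vector.
#' @export
dichotomize <- function(class_level, cutoff = 2L) {
  cutoff <- check_cutoff(cutoff)
  stopifnot(all(class_level %in% 0:6))
  class_level >= cutoff
}

check_cutoff <- function(cutoff) {
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff != floor(cutoff) ||
      cutoff < 1 || cutoff > 6) {
    mast_abort("cutoff must be a single integer in 1..6", "mast_invalid_cutoff")
  }
  as.integer(cutoff)
}

#' Construct a paired 2x2 table
#'
#' Cell counts after dichotomizing both sides of a matched-pair set:
#' `n_pp` both positive, `n_pn` A-positive/B-negative, `n_np`
#' A-negative/B-positive, `n_nn` both negative.
#'
#' @param n_pp,n_pn,n_np,n_nn nonnegative integer cell counts.
#' @return object of class `paired_table` with `N = n_pp+n_pn+n_np+n_nn`.
#' @export
paired_table <- function(n_pp, n_pn, n_np, n_nn) {
  cells <- c(n_pp = n_pp, n_pn = n_pn, n_np = n_np, n_nn = n_nn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    mast_abort("cell counts must be nonnegative integers", "mast_invalid_table")
  }
  structure(as.list(c(cells, N = sum(cells))), class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  m <- matrix(c(x$n_pp, x$n_pn, x$n_np, x$n_nn), 2, 2, byrow = TRUE,
              dimnames = list(A = c("+", "-"), B = c("+", "-")))
  cat(sprintf("<paired_table> N=%d\n", x$N))
  print(m)
  invisible(x)
}

#' Tabulate matched pairs into a 2x2 table at a cutoff
#'
#' @param pairs data.frame with `class_a` and `class_b` columns (e.g. from
#'   [pairs_for_allergen()]), or a `pair_set` whose full pair collection is
#'   tabulated.
#' @param cutoff minimal class counted positive.
#' @return a [paired_table()]; the four cells partition the pairs.
#' @export
tabulate_pairs <- function(pairs, cutoff = 2L) {
  if (inherits(pairs, "pair_set")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs), all(c("class_a", "class_b") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    mast_abort("no pairs to tabulate", "mast_empty_comparison")
  }
  a <- dichotomize(pairs$class_a, cutoff)
  b <- dichotomize(pairs$class_b, cutoff)
  paired_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

check_table <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  if (table$N < 1) {
    mast_abort("empty table: statistics undefined for N = 0", "mast_empty_comparison")
  }
  table
}

#' Total agreement percentage
#'
#' `(N - discordant) * 100 / N`: the share of pairs on which the two
#' analyzers agree after dichotomization. Inflated when positives are rare;
#' read it together with [concordant_positive_rate()].
#'
#' @param table a [paired_table()].
#' @return percentage in `[0, 100]` (full precision; round only for display).
#' @export
total_agreement <- function(table) {
  check_table(table)
  (table$N - table$n_pn - table$n_np) * 100 / table$N
}

#' Concordant positive rate
#'
#' `n_pp * 100 / N`: the share of pairs positive on both analyzers. Guards
#' against agreement driven purely by shared negatives.
#'
#' @param table a [paired_table()].
#' @return percentage in `[0, 100]`.
#' @export
concordant_positive_rate <- function(table) {
  check_table(table)
  table$n_pp * 100 / table$N
}

# Cell proportions and marginals, in the orientation used throughout:
# rows = analyzer A (+,-), cols = analyzer B (+,-).
table_props <- function(table) {
  N <- table$N
  p <- matrix(c(table$n_pp, table$n_pn, table$n_np, table$n_nn) / N, 2, 2,
              byrow = TRUE)
  list(p = p, row = rowSums(p), col = colSums(p), N = N)
}

kappa_undefined <- function(table) {
  # p_e = 1 iff both marginals are degenerate on the same category:
  # all pairs concordant-positive or all concordant-negative.
  table$n_pp == table$N || table$n_nn == table$N
}

#' Cohen's kappa for a paired 2x2 table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (n_pp + n_nn)/N` and chance agreement `p_e` from the
#' product of the marginals. Undefined (returns `NA`) when `p_e = 1`, i.e.
#' all pairs concordant in the same category.
#'
#' @param table a [paired_table()].
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(table) {
  check_table(table)
  if (kappa_undefined(table)) return(NA_real_)
  tp <- table_props(table)
  p_o <- tp$p[1, 1] + tp$p[2, 2]
  p_e <- sum(tp$row * tp$col)
  (p_o - p_e) / (1 - p_e)
}

#' Delta-method standard error of Cohen's kappa
#'
#' Large-sample standard error of the kappa estimate
#' (Fleiss, Cohen & Everitt 1969):
#' `SE = sqrt(T1 + T2 - T3) / ((1 - p_e) * sqrt(N))` with
#' `T1 = sum_i p_ii * [1 - (p_i. + p_.i)(1 - k)]^2`,
#' `T2 = (1 - k)^2 * sum_{i != j} p_ij (p_.i + p_j.)^2`,
#' `T3 = [k - p_e (1 - k)]^2`.
#' This is the variance used by standard statistical packages for kappa
#' confidence intervals; for degenerate one-sided single-discordance tables
#' the three terms cancel exactly and the SE is 0.
#'
#' @param table a [paired_table()].
#' @param kappa the kappa estimate for `table`; computed if not supplied.
#' @return nonnegative SE, or `NA` when kappa is undefined.
#' @export
kappa_se <- function(table, kappa = cohen_kappa(table)) {
  check_table(table)
  if (is.na(kappa)) return(NA_real_)
  tp <- table_props(table)
  p <- tp$p
  p_e <- sum(tp$row * tp$col)
  k <- kappa
  t1 <- sum(diag(p) * (1 - (tp$row + tp$col) * (1 - k))^2)
  t2 <- (1 - k)^2 * (p[1, 2] * (tp$col[1] + tp$row[2])^2 +
                       p[2, 1] * (tp$col[2] + tp$row[1])^2)
  t3 <- (k - p_e * (1 - k))^2
  num <- t1 + t2 - t3
  # the three terms cancel exactly for degenerate one-sided tables; snap
  # floating residue of that cancellation to zero
  if (num <= 1e-12 * (t1 + t2 + t3)) num <- 0
  sqrt(num / ((1 - p_e)^2 * tp$N))
}

#' Normal-approximation confidence interval for kappa
#'
#' `kappa +/- z * SE` with `z` the standard-normal quantile for the chosen
#' level. Bounds are deliberately NOT truncated to `[-1, 1]` by default:
#' published comparison tables print upper bounds such as 1.28, and
#' truncation would hide the small-sample character of the interval.
#'
#' @param kappa kappa estimate.
#' @param se its standard error.
#' @param level confidence level in (0, 1); default 0.95.
#' @param clip truncate bounds to `[-1, 1]`? Default `FALSE`.
#' @return named numeric `c(low, high)`, or both `NA` if inputs are `NA`.
#' @export
kappa_ci <- function(kappa, se, level = 0.95, clip = FALSE) {
  stopifnot(length(level) == 1, level > 0, level < 1)
  if (is.na(kappa) || is.na(se)) return(c(low = NA_real_, high = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(low = kappa - z * se, high = kappa + z * se)
  if (clip) ci <- pmin(pmax(ci, -1), 1)
  ci
}

#' Full agreement summary for a set of matched pairs
#'
#' Composes dichotomization, tabulation, total agreement, concordant
#' positive rate, kappa, its SE and confidence interval. All fields are at
#' full floating precision; apply reporting rounding (percentages 1 dp,
#' kappa terms 2 dp, half away from zero) only at the display layer, e.g.
#' via [format_agreement_report()].
#'
#' @param pairs data.frame of matched pairs (or a `pair_set`).
#' @param cutoff minimal class counted positive.
#' @param level confidence level for the kappa interval.
#' @param clip_ci truncate interval to `[-1, 1]`?
#' @return object of class `agreement_summary`: list with `table`,
#'   `agreement_pct`, `concordant_positive_pct`, `kappa`, `kappa_se`,
#'   `ci_low`, `ci_high`, `z`, `n`. Kappa fields are `NA` when undefined.
#' @export
summarize_agreement <- function(pairs, cutoff = 2L, level = 0.95,
                                clip_ci = FALSE) {
  tab <- tabulate_pairs(pairs, cutoff)
  k <- cohen_kappa(tab)
  se <- kappa_se(tab, k)
  ci <- kappa_ci(k, se, level = level, clip = clip_ci)
  structure(
    list(table = tab,
         agreement_pct = total_agreement(tab),
         concordant_positive_pct = concordant_positive_rate(tab),
         kappa = k, kappa_se = se,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         z = stats::qnorm(1 - (1 - level) / 2), n = tab$N),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> N=%d  agreement=%.1f%%  CPR=%.1f%%\n",
              x$n, round_half_up(x$agreement_pct, 1),
              round_half_up(x$concordant_positive_pct, 1)))
  if (is.na(x$kappa)) {
    cat("  kappa: undefined (all pairs concordant in one category)\n")
  } else {
    cat(sprintf("  kappa=%.2f  SE=%.2f  CI(%.2f to %.2f)\n",
                round_half_up(x$kappa, 2), round_half_up(x$kappa_se, 2),
                round_half_up(x$ci_low, 2), round_half_up(x$ci_high, 2)))
  }
  invisible(x)
}

#' Per-allergen agreement report for a comparison
#'
#' One row per allergen in the pair set, mirroring the layout of published
#' comparison tables (allergen, N, agreement %, concordant positive rate %,
#' kappa, SE, CI bounds). Values are full precision; see
#' [format_agreement_report()] for display rounding.
#'
#' @param pair_set a [build_pair_set()] result.
#' @inheritParams summarize_agreement
#' @return data.frame, alphabetical by allergen.
#' @export
agreement_report <- function(pair_set, cutoff = 2L, level = 0.95,
                             clip_ci = FALSE) {
  stopifnot(inherits(pair_set, "pair_set"))
  allergens <- sort(unique(pair_set$pairs$allergen))
  rows <- lapply(allergens, function(al) {
    s <- summarize_agreement(pairs_for_allergen(pair_set, al), cutoff,
                             level = level, clip_ci = clip_ci)
    data.frame(allergen = al, n = s$n, agreement_pct = s$agreement_pct,
               concordant_positive_pct = s$concordant_positive_pct,
               kappa = s$kappa, kappa_se = s$kappa_se,
               ci_low = s$ci_low, ci_high = s$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply publication rounding to an agreement report
#'
#' Percentages to 1 decimal place, kappa/SE/CI to 2, half away from zero;
#' undefined kappa prints as `"NA"`.
#'
#' @param report data.frame from [agreement_report()].
#' @return data.frame of character columns ready for printing or TSV export.
#' @export
format_agreement_report <- function(report) {
  fmt <- function(x, d) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"),
                                                       round_half_up(x, d)))
  data.frame(
    allergen = report$allergen, n = report$n,
    agreement_pct = fmt(report$agreement_pct, 1),
    concordant_positive_pct = fmt(report$concordant_positive_pct, 1),
    kappa = fmt(report$kappa, 2), kappa_se = fmt(report$kappa_se, 2),
    ci_low = fmt(report$ci_low, 2), ci_high = fmt(report$ci_high, 2)
  )
}
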