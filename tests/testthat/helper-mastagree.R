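# Shared test helpers: independent oracles and small generators.

# Independent kappa oracle: observed agreement by direct matching, chance
# agreement by brute-force enumeration of all N^2 cross-pairings of the two
# analyzers' calls. Never touches the package's closed-form p_e.
oracle_kappa <- function(tab) {
  a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(tab$n_pp, tab$n_pn, tab$n_np, tab$n_nn))
  b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(tab$n_pp, tab$n_pn, tab$n_np, tab$n_nn))
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(outer(a, b, `==`))
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# All 2x2 paired tables with total N (compositions of N into 4 cells).
all_tables <- function(n) {
  out <- list()
  for (pp in 0:n) for (pn in 0:(n - pp)) for (np in 0:(n - pp - pn)) {
    out[[length(out) + 1]] <- paired_table(pp, pn, np, n - pp - pn - np)
  }
  out
}

# Random matched-pair data.frame with class levels 0-6.
random_pairs <- function(n) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             allergen = "test allergen",
             class_a = sample(0:6, n, replace = TRUE),
             class_b = sample(0:6, n, replace = TRUE))
}

transpose_table <- function(tab) {
  paired_table(tab$n_pp, tab$n_np, tab$n_pn, tab$n_nn)
}

# Minimal registry used by I/O and pairing tests.
toy_registry <- function() {
  panel_registry(
    panels = list(
      A = list(food = c("dermatophagoides farinae", "cat", "milk"),
               inhalant = c("dermatophagoides farinae", "cat")),
      B = list(food = c("dermatophagoides farinae", "cat", "milk"),
               inhalant = c("dermatophagoides farinae", "cat"))
    ),
    aliases = c("d. farinae" = "dermatophagoides farinae",
                "d. farina" = "dermatophagoides farinae")
  )
}

toy_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], analyzer = r[[2]], panel = r[[3]],
               allergen = r[[4]], class = r[[5]])
  }))
}
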