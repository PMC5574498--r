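# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
mast_abort <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "mast_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

mast_warn <- function(message, class) {
  warning(structure(
    class = c(class, "mast_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Round half away from zero
#'
#' Reporting-layer rounding. Differs from [round()], which rounds half to
#' even: printed tables in method-comparison reports conventionally round
#' 0.915 to 0.92. A half-ulp guard absorbs binary representation error
#' (e.g. 95.25 stored as 95.24999...).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Positive-integer stream id in [1, 2^31 - 2] derived from (seed, label).
# Used to give each simulated allergen its own reproducible substream so that
# adding or removing one allergen does not perturb the draws of the others.
substream_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (b in utf8ToInt(enc2utf8(label))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize raw allergen spellings: case fold, trim, collapse internal runs
# of whitespace. This is the key on which aliases are matched.
squash_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}
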