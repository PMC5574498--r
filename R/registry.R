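# Panel registry: which allergens each analyzer carries per panel type, and
# how raw spellings map onto canonical allergen names.

#' Construct a panel registry
#'
#' A registry declares, for each analyzer, the set of canonical allergen
#' names on its food and inhalant panels, together with an alias map that
#' resolves raw spellings (case-, whitespace- and punctuation-drifted) to
#' canonical names. All dataset validation runs against a registry.
#'
#' @param panels named list: `analyzer_id -> list(food = chr, inhalant = chr)`.
#'   Allergen names are canonicalized (lower case, trimmed, internal
#'   whitespace collapsed) on construction.
#' @param aliases named character vector mapping raw spelling (after the same
#'   normalization) to canonical name, or `NULL` for none.
#' @param expected_counts optional named list `analyzer_id -> list(food = n,
#'   inhalant = n)` of advertised panel sizes. Mismatches between the
#'   advertised size and the registered set emit a warning (soft check), not
#'   an error, because published comparisons rarely enumerate full panels.
#' @return an object of class `panel_registry`.
#' @seealso [default_registry()], [canonicalize_allergen()]
#' @export
panel_registry <- function(panels, aliases = NULL, expected_counts = NULL) {
  stopifnot(is.list(panels), length(panels) >= 1, !is.null(names(panels)))
  panels <- lapply(panels, function(p) {
    stopifnot(is.list(p))
    bad <- setdiff(names(p), c("food", "inhalant"))
    if (length(bad) > 0) {
      mast_abort(sprintf("unknown panel type(s): %s", paste(bad, collapse = ", ")),
                 "mast_invalid_registry")
    }
    lapply(p, function(a) sort(unique(squash_name(a))))
  })
  if (!is.null(aliases)) {
    stopifnot(is.character(aliases), !is.null(names(aliases)))
    aliases <- stats::setNames(squash_name(aliases),
                               squash_name(names(aliases)))
    if (anyDuplicated(names(aliases))) {
      mast_abort("duplicate alias keys after normalization", "mast_invalid_registry")
    }
  } else {
    aliases <- character(0)
  }
  reg <- structure(
    list(panels = panels, aliases = aliases,
         analyzers = names(panels)),
    class = "panel_registry"
  )
  if (!is.null(expected_counts)) {
    for (an in intersect(names(expected_counts), names(panels))) {
      for (pn in intersect(names(expected_counts[[an]]), names(panels[[an]]))) {
        have <- length(panels[[an]][[pn]])
        want <- expected_counts[[an]][[pn]]
        if (have != want) {
          mast_warn(sprintf(
            "analyzer '%s' %s panel: %d allergens registered, %d advertised",
            an, pn, have, want), "mast_panel_count_mismatch")
        }
      }
    }
  }
  reg
}

#' @export
print.panel_registry <- function(x, ...) {
  cat("<panel_registry>\n")
  for (an in x$analyzers) {
    sizes <- vapply(x$panels[[an]], length, integer(1))
    cat(sprintf("  %s: %s\n", an,
                paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  }
  cat(sprintf("  aliases: %d\n", length(x$aliases)))
  invisible(x)
}

#' Resolve a raw allergen spelling to its canonical name
#'
#' Normalizes (case fold, trim, collapse whitespace), then applies the
#' registry alias map. Canonical names resolve to themselves, so the mapping
#' is idempotent. Vectorized.
#'
#' @param raw character vector of raw allergen labels.
#' @param registry a [panel_registry()].
#' @param on_unknown `"error"` (default) raises a condition of class
#'   `mast_unknown_allergen`; `"na"` returns `NA` for unmapped names.
#' @return character vector of canonical names.
#' @export
canonicalize_allergen <- function(raw, registry,
                                  on_unknown = c("error", "na")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(registry, "panel_registry"))
  if (any(!nzchar(trimws(raw)))) {
    mast_abort("empty allergen name", "mast_unknown_allergen")
  }
  key <- squash_name(raw)
  out <- ifelse(key %in% names(registry$aliases),
                unname(registry$aliases[key]), key)
  known <- registry_allergens(registry)
  miss <- !(out %in% known)
  if (any(miss)) {
    if (on_unknown == "error") {
      mast_abort(sprintf("unknown allergen(s): %s",
                         paste(unique(raw[miss]), collapse = ", ")),
                 "mast_unknown_allergen")
    }
    out[miss] <- NA_character_
  }
  out
}

# All canonical names registered anywhere.
registry_allergens <- function(registry) {
  unique(unlist(lapply(registry$panels, unlist), use.names = FALSE))
}

# Canonical names registered for one (analyzer, panel).
registry_panel <- function(registry, analyzer, panel) {
  if (!analyzer %in% registry$analyzers) {
    mast_abort(sprintf("unknown analyzer '%s' (registered: %s)", analyzer,
                       paste(registry$analyzers, collapse = ", ")),
               "mast_unknown_analyzer")
  }
  registry$panels[[analyzer]][[panel]] %||% character(0)
}

# ---------------------------------------------------------------------------
# Default registry: four immunoblot MAST analyzers. Panel contents are the
# union of allergen names appearing in published pairwise comparisons of
# these instruments; advertised panel sizes (food/inhalant) are larger, so
# the advertised counts are kept as soft checks only.

tab_food_common <- c(
  "alternaria alternata", "barley meal", "beef", "birch-alder mix",
  "buck-wheat", "candida albicans", "cat", "cheddar cheese", "chicken",
  "citrus mix", "cladosporium herbarum", "cockroach", "codfish", "crab",
  "dermatophagoides farinae", "dermatophagoides pteronyssinus", "dog",
  "egg white", "garlic", "house dust", "japanese hop", "mackerel", "milk",
  "mugwort", "oak white", "onion", "peach", "peanut", "pork", "ragweed",
  "rice", "rye pollens", "salmon", "shrimp", "soy bean", "tomato", "tuna",
  "wheat flour", "yeast, bakers"
)

tab_inh_common <- c(
  "acacia", "alternaria alternata", "ash mix", "aspergillus fumigatus",
  "bermuda grass", "birch-alder mix", "cat", "cladosporium herbarum",
  "cockroach", "crab", "dandelion", "dermatophagoides farinae",
  "dermatophagoides pteronyssinus", "dog", "egg white", "goldenrod",
  "hazelnut", "house dust", "japanese cedar", "japanese hop", "mackerel",
  "milk", "mugwort", "oak white", "orchard grass", "oxeye daisy", "peach",
  "penicillium notatum", "pigweed", "pine", "poplar mix", "ragweed", "reed",
  "russian thistle", "rye pollens", "sallow willow", "shrimp", "soy bean",
  "sweet vernal grass", "sycamore mix", "timothy grass"
)

# Extra names seen only in the newer-analyzer vs reference comparisons.
tab_food_extra <- c(
  "anchovy", "banana", "bromelain (ccd)", "chestnut", "clam", "cucumber",
  "kiwi", "mango", "mussel", "potato", "pupa, silk cocoon", "storage mite"
)
tab_inh_extra <- c(
  "bromelain (ccd)", "latex", "rabbit", "redtop, bent grass", "storage mite",
  "yellow jacket (wasp)"
)

# Analyzer-specific allergens (present on one analyzer's panel only, within
# a panel type).
spec_smart2_food  <- c("alder", "celery", "maize", "mushroom", "sesame", "squid")
spec_protia_food  <- c("almond", "latex", "lilac", "redtop, bent grass",
                       "wool", "yellow jacket (wasp)")
spec_rida_food    <- c("cacao", "chocolate")
spec_smart2_inh   <- c("acarus siro", "alder", "apple", "cacao",
                       "english plantain", "guinea pig", "hamster",
                       "hinoki cypress", "honey bee", "horse", "maize",
                       "sesame", "sheep")
spec_protia_inh   <- c("chestnut", "chocolate", "clam", "cucumber", "kiwi",
                       "lilac", "mango", "mussel", "wool")
spec_rida_inh     <- c("anchovy")

default_aliases <- c(
  "d. farinae"               = "dermatophagoides farinae",
  "d farinae"                = "dermatophagoides farinae",
  "d. farina"                = "dermatophagoides farinae",
  "dermatophagoides farina"  = "dermatophagoides farinae",
  "d. pteronyssinus"         = "dermatophagoides pteronyssinus",
  "d pteronyssinus"          = "dermatophagoides pteronyssinus",
  "buckwheat"                = "buck-wheat",
  "birch alder mix"          = "birch-alder mix",
  "weat flour"               = "wheat flour",
  "yeast"                    = "yeast, bakers",
  "bakers yeast"             = "yeast, bakers",
  "yeast bakers"             = "yeast, bakers",
  "soybean"                  = "soy bean",
  "bromelain"                = "bromelain (ccd)",
  "pupa silk cocoon"         = "pupa, silk cocoon",
  "pupa"                     = "pupa, silk cocoon",
  "redtop bent grass"        = "redtop, bent grass",
  "redtop"                   = "redtop, bent grass",
  "yellow jacket"            = "yellow jacket (wasp)",
  "wasp"                     = "yellow jacket (wasp)"
)

#' Default registry for the four reference MAST analyzers
#'
#' Registers `alloscreen` (AdvanSure AlloScreen), `smart2` (AdvanSure
#' Allostation Smart II), `protia` (PROTIA Allergy-Q) and `rida` (RIDA
#' Allergy Screen). Panel contents are reconstructed from published pairwise
#' comparisons, so each registered panel is a subset of the instrument's
#' advertised panel; with `check_counts = TRUE` the advertised sizes
#' (40/60/44/60 allergens per panel) are compared against the registered
#' sets and mismatches warn.
#'
#' @param check_counts warn when registered panel sizes differ from the
#'   advertised instrument panel sizes. Default `FALSE` (the defaults are
#'   known to be partial reconstructions).
#' @return a [panel_registry()].
#' @export
default_registry <- function(check_counts = FALSE) {
  other_spec_food <- list(
    alloscreen = c(spec_smart2_food, spec_protia_food, spec_rida_food),
    smart2     = c(spec_protia_food, spec_rida_food),
    protia     = c(spec_smart2_food, spec_rida_food),
    rida       = c(spec_smart2_food, spec_protia_food)
  )
  other_spec_inh <- list(
    alloscreen = c(spec_smart2_inh, spec_protia_inh, spec_rida_inh),
    smart2     = c(spec_protia_inh, spec_rida_inh),
    protia     = c(spec_smart2_inh, spec_rida_inh),
    rida       = c(spec_smart2_inh, spec_protia_inh)
  )
  own_food <- list(alloscreen = character(0), smart2 = spec_smart2_food,
                   protia = spec_protia_food, rida = spec_rida_food)
  own_inh  <- list(alloscreen = character(0), smart2 = spec_smart2_inh,
                   protia = spec_protia_inh, rida = spec_rida_inh)
  base_food <- list(alloscreen = tab_food_common,
                    smart2 = c(tab_food_common, tab_food_extra),
                    protia = c(tab_food_common, tab_food_extra),
                    rida   = c(tab_food_common, tab_food_extra))
  base_inh  <- list(alloscreen = tab_inh_common,
                    smart2 = c(tab_inh_common, tab_inh_extra),
                    protia = c(tab_inh_common, tab_inh_extra),
                    rida   = c(tab_inh_common, tab_inh_extra))
  panels <- lapply(c(alloscreen = "alloscreen", smart2 = "smart2",
                     protia = "protia", rida = "rida"), function(an) {
    list(
      food = c(setdiff(base_food[[an]], other_spec_food[[an]]), own_food[[an]]),
      inhalant = c(setdiff(base_inh[[an]], other_spec_inh[[an]]), own_inh[[an]])
    )
  })
  expected <- if (check_counts) {
    list(alloscreen = list(food = 40, inhalant = 40),
         smart2 = list(food = 60, inhalant = 60),
         protia = list(food = 44, inhalant = 44),
         rida = list(food = 60, inhalant = 60))
  } else NULL
  panel_registry(panels, aliases = default_aliases, expected_counts = expected)
}
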