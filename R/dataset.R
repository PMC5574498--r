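# Long-format dataset of analyzer readings and its delimited-text I/O.
#
# One row per (patient, analyzer, panel, allergen) with a class level 0-6.
# A dataset is always validated against a panel registry at construction.

DATASET_COLUMNS <- c("patient_id", "analyzer", "panel", "allergen", "class")

#' Construct a validated dataset of analyzer readings
#'
#' @param records data.frame with columns `patient_id`, `analyzer`, `panel`
#'   (`"food"` or `"inhalant"`), `allergen`, `class` (integer 0-6). Allergen
#'   names are canonicalized through the registry alias map.
#' @param registry a [panel_registry()]; every record must name a registered
#'   analyzer and an allergen on that analyzer's panel of the given type.
#' @param provenance free-text source label(s) carried as an attribute.
#' @param on_unknown handling of allergens that do not resolve to a
#'   registered name, or resolve to one absent from the record's analyzer
#'   panel: `"error"` (default) or `"drop"` (warn and discard those rows).
#' @return `mast_dataset`: a data.frame subclass with canonical allergen
#'   names and integer class levels.
#' @export
mast_dataset <- function(records, registry = default_registry(),
                         provenance = character(0),
                         on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(DATASET_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    mast_abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
               "mast_invalid_dataset")
  }
  rec <- as.data.frame(records)[DATASET_COLUMNS]
  rec$patient_id <- as.character(rec$patient_id)
  rec$analyzer <- as.character(rec$analyzer)
  rec$panel <- as.character(rec$panel)

  cls <- suppressWarnings(as.numeric(rec$class))
  bad <- is.na(cls) | cls != floor(cls) | cls < 0 | cls > 6
  if (any(bad)) {
    mast_abort(sprintf("class level out of range 0-6 at row(s): %s (values: %s)",
                       paste(which(bad), collapse = ", "),
                       paste(unique(rec$class[bad]), collapse = ", ")),
               "mast_invalid_class")
  }
  rec$class <- as.integer(cls)

  bad_panel <- !(rec$panel %in% c("food", "inhalant"))
  if (any(bad_panel)) {
    mast_abort(sprintf("unknown panel type at row(s): %s",
                       paste(which(bad_panel), collapse = ", ")),
               "mast_invalid_dataset")
  }
  unknown_an <- setdiff(unique(rec$analyzer), registry$analyzers)
  if (length(unknown_an) > 0) {
    mast_abort(sprintf("unknown analyzer(s): %s", paste(unknown_an, collapse = ", ")),
               "mast_unknown_analyzer")
  }

  canon <- canonicalize_allergen(rec$allergen, registry, on_unknown = "na")
  in_panel <- rep(FALSE, nrow(rec))
  ok <- !is.na(canon)
  if (any(ok)) {
    in_panel[ok] <- mapply(function(a, p, al) {
      al %in% registry_panel(registry, a, p)
    }, rec$analyzer[ok], rec$panel[ok], canon[ok])
  }
  if (!all(in_panel)) {
    offending <- unique(rec$allergen[!in_panel])
    msg <- sprintf("allergen(s) not registered for their analyzer/panel: %s",
                   paste(offending, collapse = ", "))
    if (on_unknown == "error") mast_abort(msg, "mast_unknown_allergen")
    mast_warn(paste0(msg, " - dropped"), "mast_dropped_records")
    rec <- rec[in_panel, , drop = FALSE]
    canon <- canon[in_panel]
  }
  rec$allergen <- canon

  key <- paste(rec$patient_id, rec$analyzer, rec$panel, rec$allergen, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- rec[duplicated(key), DATASET_COLUMNS[1:4], drop = FALSE]
    mast_abort(sprintf("duplicate (patient, analyzer, panel, allergen) record(s): %s",
                       paste(utils::head(do.call(paste, c(dup, sep = "/")), 5),
                             collapse = "; ")),
               "mast_duplicate_record")
  }
  rownames(rec) <- NULL
  structure(rec, provenance = provenance, registry = registry,
            class = c("mast_dataset", "data.frame"))
}

#' @export
print.mast_dataset <- function(x, ...) {
  cat(sprintf("<mast_dataset> %d records, %d patients, analyzers: %s\n",
              nrow(x), length(unique(x$patient_id)),
              paste(unique(x$analyzer), collapse = ", ")))
  NextMethod()
}

# Delimiter from file extension: .tsv/.txt tab, anything else comma.
infer_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read analyzer results from delimited text
#'
#' Expects a UTF-8 header line with columns `patient_id`, `analyzer`,
#' `panel`, `allergen`, `class`. Comma- or tab-delimited, chosen by file
#' extension (`.tsv`/`.txt` tab, otherwise comma). Row order is irrelevant.
#'
#' @inheritParams mast_dataset
#' @param path input file.
#' @return a validated [mast_dataset()].
#' @export
read_results <- function(path, registry = default_registry(),
                         on_unknown = c("error", "drop")) {
  if (!file.exists(path)) {
    mast_abort(sprintf("no such file: %s", path), "mast_io_error")
  }
  df <- utils::read.table(path, sep = infer_sep(path), header = TRUE,
                          colClasses = "character", quote = "\"",
                          fileEncoding = "UTF-8", check.names = TRUE)
  mast_dataset(df, registry = registry, provenance = path,
               on_unknown = on_unknown)
}

#' Write a dataset as delimited text
#'
#' Inverse of [read_results()]: `read_results(write_results(d, p), p)`
#' reproduces `d` up to row order.
#'
#' @param dataset a [mast_dataset()].
#' @param path output file; extension selects the delimiter as in
#'   [read_results()].
#' @return `path`, invisibly.
#' @export
write_results <- function(dataset, path) {
  stopifnot(inherits(dataset, "mast_dataset"))
  utils::write.table(as.data.frame(dataset)[DATASET_COLUMNS], path,
                     sep = infer_sep(path), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
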