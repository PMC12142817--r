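#' Normalize free-text terms for exact matching
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace to
#' a single space, case-folds Latin letters, and converts full-width
#' (CJK compatibility) ASCII characters and the ideographic space to their
#' half-width equivalents. CJK ideographs are compared as-is. This is the
#' normalization applied on both sides before any lookup match: matching is
#' exact-after-normalization, never fuzzy, so every standardization step is
#' auditable.
#'
#' @param x character vector of raw terms.
#' @return character vector of normalized terms.
#' @examples
#' normalize_term(c("  Huang   Qi ", "ＡＢＣ"))
#' @export
normalize_term <- function(x) {
  x <- as.character(x)
  # full-width ASCII block U+FF01..U+FF5E -> U+0021..U+007E; U+3000 -> space
  fw <- intToUtf8(0xFF01:0xFF5E, multiple = TRUE)
  hw <- intToUtf8(0x21:0x7E, multiple = TRUE)
  x <- chartr(paste(c(fw, "　"), collapse = ""),
              paste(c(hw, " "), collapse = ""), x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  tolower(x)
}

#' Build a raw prescription record table
#'
#' Validates and types a long-format record table: one row per
#' (formula, term) pair with a field type distinguishing ingredients from
#' diagnostic, syndrome and symptom annotations.
#'
#' @param df data frame with columns `formula_id`, `raw_term`, and optionally
#'   `field_type` (defaults to `"ingredient"`) and `dose`.
#' @return a tibble of class `raw_records` with columns `formula_id`,
#'   `field_type`, `raw_term`, `dose`.
#' @export
raw_records <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("formula_id", "raw_term") %in% names(df))) {
    stop("raw record table needs columns 'formula_id' and 'raw_term'",
         call. = FALSE)
  }
  if (!"field_type" %in% names(df)) df$field_type <- "ingredient"
  if (!"dose" %in% names(df)) df$dose <- NA_real_
  bad_type <- setdiff(unique(df$field_type),
                      c("ingredient", "diagnosis", "syndrome", "symptom"))
  if (length(bad_type)) {
    stop("unknown field_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  df$formula_id <- as.character(df$formula_id)
  df$raw_term <- as.character(df$raw_term)
  keep <- nzchar(trimws(df$formula_id)) & nzchar(trimws(df$raw_term))
  n_drop <- sum(!keep)
  out <- df[keep, c("formula_id", "field_type", "raw_term", "dose")]
  attr(out, "n_blank_dropped") <- n_drop
  class(out) <- c("raw_records", class(out))
  out
}

#' Build a lookup table mapping raw terms to standardized terms
#'
#' @param raw character vector of raw/variant terms (keys; must be unique
#'   after normalization).
#' @param standard character vector of standardized terms, same length.
#' @param unmatched optional character vector of raw terms known to have no
#'   mapping.
#' @return a tibble of class `lookup_table` with columns `raw`, `standard`
#'   and an `unmatched` attribute.
#' @export
lookup_table <- function(raw, standard, unmatched = character()) {
  stopifnot(length(raw) == length(standard))
  raw_n <- normalize_term(raw)
  if (anyDuplicated(raw_n)) {
    dup <- unique(raw_n[duplicated(raw_n)])
    stop("duplicate raw terms in lookup table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(raw = raw_n, standard = as.character(standard))
  attr(out, "unmatched") <- unique(normalize_term(unmatched))
  class(out) <- c("lookup_table", class(out))
  out
}

#' Unmatched terms of a lookup table
#' @param lut a `lookup_table`.
#' @return character vector of raw terms with no standard mapping.
#' @export
unmatched_terms <- function(lut) attr(lut, "unmatched") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a raw dataset with a reference lookup table
#'
#' For every distinct raw term in the dataset, finds its standardized form in
#' the reference lookup (matching is exact after [normalize_term()]
#' normalization). Terms present in the reference's standardized vocabulary
#' but not among its keys are identity-mapped. Terms with no mapping are
#' collected in the `unmatched` attribute of the result; these are the
#' entries that still require manual standardization.
#'
#' @param raw a `raw_records` table (or data frame coercible to one).
#' @param reference a `lookup_table` serving as the standardization
#'   reference; must be non-empty.
#' @param field which field type to standardize (default `"ingredient"`).
#' @return a `lookup_table` covering every distinct raw term of the dataset:
#'   matched terms in its rows, the remainder in `unmatched_terms()`.
#' @export
make_lookup <- function(raw, reference, field = "ingredient") {
  raw <- raw_records(raw)
  if (nrow(raw) == 0L) stop("raw record table is empty", call. = FALSE)
  if (!inherits(reference, "lookup_table") || nrow(reference) == 0L) {
    stop("reference lookup table must be a non-empty lookup_table",
         call. = FALSE)
  }
  terms <- unique(normalize_term(raw$raw_term[raw$field_type == field]))
  if (length(terms) == 0L) {
    stop("no records with field_type '", field, "'", call. = FALSE)
  }
  map <- stats::setNames(reference$standard, reference$raw)
  std_vocab <- unique(reference$standard)
  hit <- terms %in% names(map)
  identity_hit <- !hit & terms %in% normalize_term(std_vocab)
  matched <- terms[hit | identity_hit]
  standards <- ifelse(matched %in% names(map), map[matched], matched)
  lookup_table(matched, unname(standards),
               unmatched = terms[!(hit | identity_hit)])
}

#' Add user terms to a reference lookup table
#'
#' Extends a reference lookup with user-supplied (raw, standard) pairs, e.g.
#' for rare herbs absent from the packaged reference. Additions identical to
#' an existing entry are ignored (idempotent); additions whose raw term is
#' already mapped to a *different* standard term are collisions and raise an
#' error naming them — an existing mapping is never silently overwritten.
#'
#' @param reference a `lookup_table` (may be empty).
#' @param additions data frame with columns `raw` and `standard` (extra
#'   attribute columns are allowed and ignored here).
#' @return the extended `lookup_table`.
#' @export
add_reference_terms <- function(reference, additions) {
  additions <- tibble::as_tibble(additions)
  stopifnot(all(c("raw", "standard") %in% names(additions)))
  if (any(!nzchar(trimws(additions$raw))) ||
      any(!nzchar(trimws(additions$standard)))) {
    stop("additions must have non-empty raw and standard fields",
         call. = FALSE)
  }
  add_raw <- normalize_term(additions$raw)
  add_std <- as.character(additions$standard)
  # dedupe identical addition rows
  keep <- !duplicated(paste0(add_raw, "\r", add_std))
  add_raw <- add_raw[keep]; add_std <- add_std[keep]
  if (anyDuplicated(add_raw)) {
    dup <- unique(add_raw[duplicated(add_raw)])
    stop("conflicting additions for raw term(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  existing <- stats::setNames(reference$standard, reference$raw)
  clash <- add_raw %in% names(existing) & existing[add_raw] != add_std
  if (any(clash)) {
    stop("collision: raw term(s) already mapped to a different standard: ",
         paste(add_raw[clash], collapse = ", "), call. = FALSE)
  }
  new <- !(add_raw %in% names(existing))
  lookup_table(c(reference$raw, add_raw[new]),
               c(reference$standard, add_std[new]),
               unmatched = unmatched_terms(reference))
}

#' Construct a formula dataset
#'
#' The central container: an ordered collection of prescriptions, each a set
#' (no duplicates) of standardized ingredient labels, with optional
#' per-formula annotations (syndrome, symptoms, doses).
#'
#' @param formulas named list of character vectors; names are formula ids,
#'   elements are ingredient sets. Duplicates within a formula are collapsed.
#' @param annotations optional tibble keyed by `formula_id`.
#' @return an object of class `formula_dataset`.
#' @export
formula_dataset <- function(formulas, annotations = NULL) {
  if (length(formulas)) {
    if (is.null(names(formulas)) || any(!nzchar(names(formulas)))) {
      stop("formulas must be a named list (names = formula ids)",
           call. = FALSE)
    }
    if (anyDuplicated(names(formulas))) {
      stop("formula ids must be unique", call. = FALSE)
    }
    formulas <- lapply(formulas, function(x) sort(unique(as.character(x))))
  } else {
    formulas <- stats::setNames(list(), character())
  }
  structure(list(formulas = formulas, annotations = annotations),
            class = "formula_dataset")
}

#' @export
print.formula_dataset <- function(x, ...) {
  n <- length(x$formulas)
  vocab <- length(unique(unlist(x$formulas)))
  cat("<formula_dataset> ", n, " formulas, ", vocab,
      " distinct ingredients\n", sep = "")
  if (n) {
    shown <- utils::head(names(x$formulas), 3)
    for (id in shown) {
      cat("  ", id, ": ",
          paste(utils::head(x$formulas[[id]], 6), collapse = ", "),
          if (length(x$formulas[[id]]) > 6) ", ..." else "", "\n", sep = "")
    }
    if (n > 3) cat("  ...\n")
  }
  invisible(x)
}

#' Number of formulas in a dataset
#' @param ds a `formula_dataset`.
#' @return integer count.
#' @export
n_formulas <- function(ds) length(ds$formulas)

#' Standardize and clean a raw prescription table
#'
#' Applies a lookup table to every term of the chosen field, collapses
#' duplicate entries within a record (a symptom list should not contain the
#' same symptom twice, nor a prescription the same herb), and assembles a
#' [formula_dataset()]. Terms absent from the lookup either raise an error
#' (default) or, with `drop_unmatched = TRUE`, are dropped with a logged
#' count. Formulas left empty after cleaning are dropped by default.
#'
#' @param raw a `raw_records` table (or coercible data frame).
#' @param lookup a `lookup_table` covering the raw terms.
#' @param field field type to clean into the ingredient sets
#'   (default `"ingredient"`).
#' @param drop_unmatched drop terms with no mapping instead of erroring.
#' @param keep_empty keep formulas whose ingredient set is empty after
#'   cleaning (default `FALSE`: drop them).
#' @return a `formula_dataset`; attributes `n_unmatched_dropped` and
#'   `n_empty_dropped` record the cleaning log, and annotation fields
#'   (syndrome/symptom/diagnosis) are carried per formula in
#'   `$annotations`.
#' @export
clean_dataset <- function(raw, lookup, field = "ingredient",
                          drop_unmatched = FALSE, keep_empty = FALSE) {
  raw <- raw_records(raw)
  stopifnot(inherits(lookup, "lookup_table"))
  rec <- raw[raw$field_type == field, ]
  if (nrow(rec) == 0L) {
    return(structure(formula_dataset(list()),
                     n_unmatched_dropped = 0L, n_empty_dropped = 0L))
  }
  terms <- normalize_term(rec$raw_term)
  map <- stats::setNames(lookup$standard, lookup$raw)
  hit <- terms %in% names(map)
  if (any(!hit)) {
    missing <- sort(unique(terms[!hit]))
    if (!drop_unmatched) {
      stop("unmatched terms (set drop_unmatched = TRUE to drop them): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  rec$std <- NA_character_
  rec$std[hit] <- unname(map[terms[hit]])
  ids <- unique(rec$formula_id)
  sets <- lapply(ids, function(id) {
    s <- rec$std[rec$formula_id == id]
    sort(unique(s[!is.na(s)]))
  })
  names(sets) <- ids
  empty <- vapply(sets, length, integer(1)) == 0L
  n_empty_dropped <- 0L
  if (!keep_empty && any(empty)) {
    n_empty_dropped <- sum(empty)
    sets <- sets[!empty]
  }
  ann <- annotate_from_records(raw, names(sets))
  structure(formula_dataset(sets, annotations = ann),
            n_unmatched_dropped = sum(!hit),
            n_empty_dropped = n_empty_dropped)
}

# collect non-ingredient fields into one annotation tibble per formula
annotate_from_records <- function(raw, ids) {
  ann_rec <- raw[raw$field_type != "ingredient" & raw$formula_id %in% ids, ]
  if (nrow(ann_rec) == 0L) return(NULL)
  ann_rec$raw_term <- normalize_term(ann_rec$raw_term)
  ann_rec <- dplyr::distinct(ann_rec, .data$formula_id, .data$field_type,
                             .data$raw_term)
  tidyr::pivot_wider(
    dplyr::group_by(ann_rec, .data$formula_id, .data$field_type),
    names_from = "field_type",
    values_from = "raw_term",
    values_fn = function(x) paste(sort(unique(x)), collapse = "|")
  )
}

#' Encode a formula dataset as a wide binary matrix
#'
#' Rows are formulas, columns ingredients, cells 0/1. The column order is
#' deterministic — descending total frequency, ties alphabetical — so that
#' downstream outputs are byte-reproducible.
#'
#' @param ds a `formula_dataset`.
#' @return integer matrix with formula ids as rownames and ingredient terms
#'   as colnames.
#' @export
to_wide <- function(ds) {
  stopifnot(inherits(ds, "formula_dataset"))
  if (n_formulas(ds) == 0L) {
    return(matrix(integer(), 0, 0))
  }
  items <- sort(unique(unlist(ds$formulas)))
  m <- vapply(items, function(it) {
    as.integer(vapply(ds$formulas, function(s) it %in% s, logical(1)))
  }, integer(n_formulas(ds)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, items))
  rownames(m) <- names(ds$formulas)
  freq <- colSums(m)
  m[, order(-freq, colnames(m)), drop = FALSE]
}

#' Decode a wide binary matrix back into a formula dataset
#'
#' Inverse of [to_wide()] on the incidence structure (annotations are not
#' representable in the wide form and are dropped).
#'
#' @param m binary matrix with formula ids as rownames and ingredient terms
#'   as colnames.
#' @return a `formula_dataset`.
#' @export
to_long <- function(m) {
  m <- as.matrix(m)
  if (length(m) && !all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    stop("non-binary cell in wide matrix (value ", m[bad], ")",
         call. = FALSE)
  }
  if (nrow(m) == 0L) return(formula_dataset(list()))
  if (is.null(rownames(m))) rownames(m) <- paste0("F", seq_len(nrow(m)))
  sets <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] == 1])
  names(sets) <- rownames(m)
  formula_dataset(sets)
}

#' Frequency table of a dataset field
#'
#' Tallies how many formulas carry each term of a field, sorted descending by
#' count with alphabetical tie-break. The relative frequency is the count
#' divided by the number of formulas.
#'
#' @param ds a `formula_dataset`.
#' @param field `"ingredient"` (counted over ingredient sets) or an
#'   annotation field (`"syndrome"`, `"symptom"`, `"diagnosis"`).
#' @return tibble with columns `term`, `count`, `relative_frequency`.
#' @export
freq_table <- function(ds, field = "ingredient") {
  stopifnot(inherits(ds, "formula_dataset"))
  if (field == "ingredient") {
    terms <- unlist(ds$formulas, use.names = FALSE)
  } else {
    ann <- ds$annotations
    if (is.null(ann) || !field %in% names(ann)) {
      stop("unknown or absent field: ", field, call. = FALSE)
    }
    terms <- unlist(strsplit(ann[[field]][!is.na(ann[[field]])], "|",
                             fixed = TRUE))
  }
  if (length(terms) == 0L) {
    return(tibble::tibble(term = character(), count = integer(),
                          relative_frequency = double()))
  }
  tab <- table(terms)
  out <- tibble::tibble(term = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$term), ]
  out$relative_frequency <- out$count / n_formulas(ds)
  out
}
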