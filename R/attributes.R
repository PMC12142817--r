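#' Build a herb attribute table
#'
#' Per-herb TCM attributes: one of the four-natures categories (the scheme
#' includes five thermal levels), a non-empty set of flavors, a non-empty set
#' of meridians, and a hierarchical efficacy class written as
#' `class/subclass`.
#'
#' @param df data frame with columns `herb`, `nature`, `flavors`
#'   (`|`-separated), `meridians` (`|`-separated), `efficacy_class`
#'   (`/`-separated hierarchy). Herb labels are standardized terms.
#' @return a tibble of class `herb_attributes`.
#' @export
herb_attributes <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("herb", "nature", "flavors", "meridians", "efficacy_class")
  if (!all(need %in% names(df))) {
    stop("attribute table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  natures <- c("cold", "cool", "neutral", "warm", "hot")
  bad <- setdiff(unique(df$nature[!is.na(df$nature)]), natures)
  if (length(bad)) {
    stop("unknown nature value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$herb)) {
    stop("duplicate herb rows in attribute table", call. = FALSE)
  }
  df$herb <- normalize_term(df$herb)
  class(df) <- c("herb_attributes", class(df))
  df
}

split_multi <- function(x, sep = "|") {
  if (length(x) == 0L) return(list())
  strsplit(ifelse(is.na(x), "", x), sep, fixed = TRUE)
}

# tally one attribute over a dataset: unweighted = distinct herbs carrying a
# category, weighted = herb occurrence counts across formulas summed per
# category; multi-valued attributes contribute to every category they carry
tally_attribute <- function(values_per_herb, occ) {
  rows <- mapply(function(vals, herb) {
    vals <- vals[nzchar(vals)]
    if (!length(vals)) return(NULL)
    tibble::tibble(category = vals, herb = herb)
  }, values_per_herb, names(values_per_herb), SIMPLIFY = FALSE)
  rows <- dplyr::bind_rows(rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble::tibble(category = character(),
                          unweighted_count = integer(),
                          weighted_count = integer()))
  }
  rows$occ <- occ[rows$herb]
  out <- dplyr::summarise(dplyr::group_by(rows, .data$category),
                          unweighted_count = dplyr::n_distinct(.data$herb),
                          weighted_count = as.integer(sum(.data$occ)),
                          .groups = "drop")
  out[order(-out$weighted_count, out$category), ]
}

check_attr_coverage <- function(ds, attrs, skip_missing) {
  herbs <- unique(unlist(ds$formulas))
  missing <- setdiff(herbs, attrs$herb)
  if (length(missing) && !skip_missing) {
    stop("herbs absent from attribute table (set skip_missing = TRUE): ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  intersect(herbs, attrs$herb)
}

#' Nature, flavor and meridian statistics of a dataset
#'
#' For each category of the three property schemes, reports how many
#' *distinct* herbs in the dataset carry it (unweighted) and the sum of those
#' herbs' occurrence counts across formulas (weighted). Flavors and meridians
#' are multi-valued: a herb contributes to every category it carries; each
#' herb has exactly one nature.
#'
#' @param ds a `formula_dataset`.
#' @param attrs a [herb_attributes()] table covering the dataset's herbs.
#' @param skip_missing skip (and log) herbs absent from `attrs` instead of
#'   erroring.
#' @return list of three tibbles (`nature`, `flavor`, `meridian`), each with
#'   columns `category`, `unweighted_count`, `weighted_count`; attribute
#'   `missing_herbs` lists skipped herbs.
#' @export
calc_property <- function(ds, attrs, skip_missing = FALSE) {
  stopifnot(inherits(ds, "formula_dataset"))
  attrs <- herb_attributes(attrs)
  herbs <- check_attr_coverage(ds, attrs, skip_missing)
  occ <- freq_table(ds)
  occ <- stats::setNames(occ$count, occ$term)[herbs]
  at <- attrs[match(herbs, attrs$herb), ]
  nature <- stats::setNames(as.list(ifelse(is.na(at$nature), "", at$nature)),
                            herbs)
  out <- list(
    nature   = tally_attribute(nature, occ),
    flavor   = tally_attribute(stats::setNames(split_multi(at$flavors),
                                               herbs), occ),
    meridian = tally_attribute(stats::setNames(split_multi(at$meridians),
                                               herbs), occ)
  )
  attr(out, "missing_herbs") <-
    sort(setdiff(unique(unlist(ds$formulas)), attrs$herb))
  out
}

#' Efficacy classification statistics of a dataset
#'
#' Tallies herbs per efficacy class, weighted and unweighted as in
#' [calc_property()]. The hierarchical `class/subclass` labels are kept
#' intact and additionally split into `parent` and `child` columns so the
#' table is ready for sunburst-style plotting.
#'
#' @inheritParams calc_property
#' @return tibble with columns `efficacy_class`, `parent`, `child`,
#'   `unweighted_count`, `weighted_count`; attribute `missing_herbs`.
#' @export
calc_func <- function(ds, attrs, skip_missing = FALSE) {
  stopifnot(inherits(ds, "formula_dataset"))
  attrs <- herb_attributes(attrs)
  herbs <- check_attr_coverage(ds, attrs, skip_missing)
  occ <- freq_table(ds)
  occ <- stats::setNames(occ$count, occ$term)[herbs]
  at <- attrs[match(herbs, attrs$herb), ]
  eff <- ifelse(is.na(at$efficacy_class), "", at$efficacy_class)
  known <- nzchar(eff)
  tab <- tally_attribute(stats::setNames(as.list(eff[known]), herbs[known]),
                         occ)
  names(tab)[names(tab) == "category"] <- "efficacy_class"
  parts <- strsplit(tab$efficacy_class, "/", fixed = TRUE)
  tab$parent <- vapply(parts, `[`, character(1), 1)
  tab$child <- vapply(parts, function(p) {
    if (length(p) > 1) paste(p[-1], collapse = "/") else NA_character_
  }, character(1))
  out <- tab[, c("efficacy_class", "parent", "child",
                 "unweighted_count", "weighted_count")]
  attr(out, "missing_herbs") <-
    sort(setdiff(unique(unlist(ds$formulas)), attrs$herb))
  attr(out, "no_efficacy") <- sort(herbs[!known])
  out
}
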