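#' Read a prescription table from disk
#'
#' Two dialects are supported. `long`: one row per (formula, term) pair with
#' header columns `formula_id`, `ingredient` (or `raw_term`) and optionally
#' `dose`, `syndrome`, `symptom`, `diagnosis`. `wide`: `formula_id` first
#' column, one 0/1 column per ingredient. CSV/TSV are detected by
#' extension; `.xlsx` is read via readxl when installed. All text is
#' treated as UTF-8.
#'
#' @param path input file.
#' @param dialect `"long"` or `"wide"`.
#' @return for `long`, a `raw_records` table (annotation columns unpivoted
#'   into `field_type` rows); for `wide`, a binary integer matrix.
#' @export
read_formula_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx needs the readxl package", call. = FALSE)
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else if (ext == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (dialect == "long") {
    if (!"formula_id" %in% names(df)) {
      stop("long input needs a 'formula_id' column", call. = FALSE)
    }
    term_col <- intersect(c("ingredient", "raw_term"), names(df))[1]
    if (is.na(term_col)) {
      stop("long input needs an 'ingredient' (or 'raw_term') column",
           call. = FALSE)
    }
    rec <- tibble::tibble(formula_id = as.character(df$formula_id),
                          field_type = "ingredient",
                          raw_term = as.character(df[[term_col]]),
                          dose = if ("dose" %in% names(df))
                            as.numeric(df$dose) else NA_real_)
    for (f in intersect(c("syndrome", "symptom", "diagnosis"), names(df))) {
      extra <- df[!is.na(df[[f]]) & nzchar(as.character(df[[f]])), ]
      if (nrow(extra)) {
        rec <- dplyr::bind_rows(rec, tibble::tibble(
          formula_id = as.character(extra$formula_id), field_type = f,
          raw_term = as.character(extra[[f]]), dose = NA_real_))
      }
    }
    raw_records(rec)
  } else {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop("non-binary cell at row ", rc[1], ", column '",
           colnames(m)[rc[2]], "' (value ", m[bad[1]], ")", call. = FALSE)
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
  }
}

#' Read a 2-column lookup table file
#' @param path CSV with columns `raw`, `standard`.
#' @return a `lookup_table`.
#' @export
read_lookup <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("raw", "standard") %in% names(df))) {
    stop("lookup file needs columns 'raw' and 'standard'", call. = FALSE)
  }
  lookup_table(df$raw, df$standard)
}

#' Write a formula dataset as a long CSV
#' @param ds a `formula_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "formula_dataset"))
  rows <- tibble::tibble(
    formula_id = rep(names(ds$formulas), lengths(ds$formulas)),
    ingredient = unlist(ds$formulas, use.names = FALSE))
  readr::write_csv(rows, path)
  invisible(path)
}

#' Write a network as GraphML plus an edge-list CSV
#' @param g an [igraph::graph].
#' @param stem output path stem; writes `<stem>.graphml` and
#'   `<stem>_edges.csv` (and `<stem>_nodes.csv`).
#' @return character vector of paths written, invisibly.
#' @export
write_network <- function(g, stem) {
  paths <- c(paste0(stem, ".graphml"), paste0(stem, "_edges.csv"),
             paste0(stem, "_nodes.csv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  nt <- network_tables(g)
  readr::write_csv(nt$edges, paths[2])
  readr::write_csv(nt$nodes, paths[3])
  invisible(paths)
}
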