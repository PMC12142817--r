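#' Configuration for the synthetic prescription generator
#'
#' Bundles and validates the knobs of [simulate_formulas()]. Defaults model
#' a mid-sized clinical prescription collection: a 120-term vocabulary with
#' Zipf rank-frequency usage (a few workhorse herbs carrying most
#' occurrences, a long tail of rare ones), prescriptions of 6-15
#' ingredients, and optional planted core combinations standing in for the
#' recurring herb pairs and triplets real formula groups contain.
#'
#' @param n_formulas number of prescriptions to generate.
#' @param vocabulary_size size of the ingredient vocabulary (>= 2). The
#'   first terms are the packaged fixture herbs (so synonym noise has
#'   variants to draw on); beyond those, `herb_###` labels are appended.
#' @param formula_size_range integer `c(min, max)` ingredients per formula.
#' @param zipf_exponent exponent s of the Zipf rank-frequency law,
#'   p(rank r) proportional to r^-s (default 1).
#' @param planted_motifs list of `list(items = <character>, prob = <0..1>)`:
#'   each motif is included wholesale in a formula with its probability.
#' @param synonym_noise_rate per-entry probability of swapping a
#'   standardized term for one of its raw variants from the fixture lookup.
#' @param duplicate_entry_rate per-entry probability of a duplicated row
#'   (transcription noise).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_formulas = 200L, vocabulary_size = 120L,
                       formula_size_range = c(6L, 15L), zipf_exponent = 1,
                       planted_motifs = list(), synonym_noise_rate = 0,
                       duplicate_entry_rate = 0, seed = 1L) {
  stopifnot(n_formulas >= 0L, vocabulary_size >= 2L,
            length(formula_size_range) == 2L,
            formula_size_range[1] >= 1L,
            formula_size_range[1] <= formula_size_range[2],
            zipf_exponent > 0,
            synonym_noise_rate >= 0, synonym_noise_rate <= 1,
            duplicate_entry_rate >= 0, duplicate_entry_rate <= 1)
  for (mo in planted_motifs) {
    if (!is.list(mo) || is.null(mo$items) || is.null(mo$prob) ||
        mo$prob < 0 || mo$prob > 1) {
      stop("each motif must be list(items = <character>, prob = <0..1>)",
           call. = FALSE)
    }
  }
  structure(list(n_formulas = as.integer(n_formulas),
                 vocabulary_size = as.integer(vocabulary_size),
                 formula_size_range = as.integer(formula_size_range),
                 zipf_exponent = zipf_exponent,
                 planted_motifs = planted_motifs,
                 synonym_noise_rate = synonym_noise_rate,
                 duplicate_entry_rate = duplicate_entry_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_vocabulary <- function(vocabulary_size) {
  base <- load_fixture("attributes")$herb
  if (vocabulary_size <= length(base)) {
    base[seq_len(vocabulary_size)]
  } else {
    c(base, sprintf("herb_%03d", seq_len(vocabulary_size - length(base))))
  }
}

#' Generate a synthetic prescription dataset
#'
#' Draws `n_formulas` prescriptions as follows: each planted motif is
#' included wholesale with its inclusion probability; the remaining slots
#' (up to a uniformly drawn formula size) are filled by sampling distinct
#' background ingredients with Zipf rank-frequency weights. Optional
#' synonym noise rewrites an entry as a raw variant taken from the packaged
#' fixture lookup, and duplicate noise repeats entries — the two
#' transcription artifacts the standardization stage is there to undo, so
#' with both rates at 0 [clean_dataset()] is the identity on this output.
#' The ground truth (motifs, term map, vocabulary) is returned alongside;
#' nothing has to be reverse-engineered from the records.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result`: `records` (a `raw_records` long
#'   table), `truth` (list: `motifs`, `motif_membership` logical matrix
#'   formulas x motifs, `term_map` raw->standard for the noise variants
#'   used, `vocabulary`, `config`).
#' @export
simulate_formulas <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  vocab <- sim_vocabulary(cfg$vocabulary_size)
  for (mo in cfg$planted_motifs) {
    if (!all(mo$items %in% vocab)) {
      stop("motif items outside vocabulary: ",
           paste(setdiff(mo$items, vocab), collapse = ", "), call. = FALSE)
    }
    if (length(mo$items) > cfg$formula_size_range[2]) {
      stop("motif larger than maximum formula size", call. = FALSE)
    }
  }
  lut <- load_fixture("lookup")
  variants <- split(lut$raw, lut$standard)
  ranks <- seq_along(vocab)
  zipf_w <- ranks^(-cfg$zipf_exponent)

  set.seed(cfg$seed)
  n <- cfg$n_formulas
  n_motifs <- length(cfg$planted_motifs)
  membership <- matrix(FALSE, n, n_motifs)
  rows_id <- character(); rows_term <- character()
  used_map <- character()
  if (n > 0) {
    for (i in seq_len(n)) {
      size <- sample(seq.int(cfg$formula_size_range[1],
                             cfg$formula_size_range[2]), 1L)
      items <- character()
      for (mi in seq_len(n_motifs)) {
        mo <- cfg$planted_motifs[[mi]]
        if (stats::runif(1) < mo$prob) {
          membership[i, mi] <- TRUE
          items <- union(items, mo$items)
        }
      }
      need <- max(size - length(items), 0L)
      if (need > 0L) {
        pool <- setdiff(vocab, items)
        w <- zipf_w[match(pool, vocab)]
        items <- c(items, sample(pool, min(need, length(pool)),
                                 prob = w))
      }
      terms <- items
      if (cfg$synonym_noise_rate > 0) {
        for (j in seq_along(terms)) {
          v <- variants[[terms[j]]]
          if (length(v) && stats::runif(1) < cfg$synonym_noise_rate) {
            pick <- sample(v, 1L)
            used_map[pick] <- terms[j]
            terms[j] <- pick
          }
        }
      }
      if (cfg$duplicate_entry_rate > 0) {
        dup <- stats::runif(length(terms)) < cfg$duplicate_entry_rate
        terms <- c(terms, terms[dup])
      }
      rows_id <- c(rows_id, rep(sprintf("F%05d", i), length(terms)))
      rows_term <- c(rows_term, terms)
    }
  }
  records <- raw_records(tibble::tibble(
    formula_id = rows_id, field_type = "ingredient", raw_term = rows_term))
  structure(list(
    records = records,
    truth = list(motifs = cfg$planted_motifs,
                 motif_membership = membership,
                 term_map = used_map,
                 vocabulary = vocab,
                 config = cfg)),
    class = "sim_result")
}

#' Convert simulator output directly into a formula dataset
#'
#' Convenience wrapper: builds the identity-plus-fixture lookup over the
#' simulation vocabulary and runs [clean_dataset()] on the simulated
#' records.
#'
#' @param sim a `sim_result` from [simulate_formulas()].
#' @return a `formula_dataset`.
#' @export
sim_dataset <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  lut <- load_fixture("lookup")
  full <- lookup_table(c(lut$raw, sim$truth$vocabulary),
                       c(lut$standard, sim$truth$vocabulary))
  clean_dataset(sim$records, full)
}

#' Load a packaged reference fixture
#'
#' The package ships three small synthetic fixtures standing in for a
#' pharmacopoeia-backed reference (which is not redistributable): a synonym
#' `lookup` table (raw variant -> standardized herb), a herb `attributes`
#' table (nature, flavors, meridians, efficacy class), and `classics`, a
#' set of well-known classical formula compositions in long format. They
#' are plain CSV under `inst/extdata/`, versioned with the package, and
#' deliberately tiny; their content is plausible but synthetic and must not
#' be used as an authoritative reference.
#'
#' @param name one of `"lookup"`, `"attributes"`, `"classics"`.
#' @return the corresponding table: a `lookup_table`, a `herb_attributes`
#'   tibble, or a `raw_records` long table of classical compositions.
#' @export
load_fixture <- function(name = c("lookup", "attributes", "classics")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      paste0("synthetic_", name, ".csv"),
                      package = "fminer", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  switch(name,
         lookup = lookup_table(df$raw, df$standard),
         attributes = herb_attributes(df),
         classics = raw_records(df))
}
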