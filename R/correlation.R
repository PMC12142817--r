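#' Phi correlation matrices over binary occurrence columns
#'
#' For every pair of selected columns of a binary incidence matrix (e.g.
#' herb x herb, or herb x symptom), computes the phi coefficient
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)) from the 2x2 contingency
#' table (a = both present, b = first only, c = second only, d = neither),
#' the chi-square p-value from the identity chi2 = n * phi^2 on 1 degree of
#' freedom, and a significance-star matrix marking `"*"` where p < 0.05.
#' Phi equals the Pearson correlation of the two binary columns.
#'
#' No multiple-testing correction is applied to the star matrix; with many
#' column pairs the stars are descriptive, not confirmatory. Zero-variance
#' columns (an item present in every formula or in none of them) have no
#' defined phi; they are reported as phi = 0 with p = 1 and listed in the
#' `flagged` element rather than propagating NaN.
#'
#' @param m binary matrix (formulas x items), e.g. from [to_wide()].
#' @param cols_a,cols_b column label sets to correlate; default all columns
#'   against all columns (symmetric herb-herb matrix).
#' @param yates apply the Yates continuity correction to the chi-square
#'   statistic (default `FALSE`, preserving the n*phi^2 identity).
#' @param star_alpha significance level for the star matrix (default 0.05).
#' @return list of class `phi_result`: `phi` (matrix), `p` (matrix, `NA` on
#'   the diagonal of a symmetric result), `stars` (character matrix),
#'   `flagged` (zero-variance column labels).
#' @export
calc_phi <- function(m, cols_a = colnames(m), cols_b = colnames(m),
                     yates = FALSE, star_alpha = 0.05) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows (formulas)", call. = FALSE)
  sel <- unique(c(cols_a, cols_b))
  if (!all(sel %in% colnames(m))) {
    stop("unknown columns: ", paste(setdiff(sel, colnames(m)), collapse = ", "),
         call. = FALSE)
  }
  sub <- m[, sel, drop = FALSE]
  if (!all(sub %in% c(0, 1))) stop("non-binary column selected", call. = FALSE)
  n <- nrow(m)
  x <- m[, cols_a, drop = FALSE]; y <- m[, cols_b, drop = FALSE]
  a <- crossprod(x, y)                       # both 1
  ra <- colSums(x); rb <- colSums(y)
  b <- outer(ra, rep(1, length(rb))) - a     # x only
  cc <- outer(rep(1, length(ra)), rb) - a    # y only
  d <- n - a - b - cc
  num <- a * d - b * cc
  den <- sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  phi <- num / den
  degenerate <- den == 0
  phi[degenerate] <- 0
  if (yates) {
    chi2 <- n * (pmax(abs(num) - n / 2, 0))^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    chi2[degenerate] <- 0
  } else {
    chi2 <- n * phi^2
  }
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[degenerate] <- 1
  stars <- matrix(ifelse(p < star_alpha, "*", ""), nrow(p), ncol(p))
  dimnames(phi) <- dimnames(p) <- dimnames(stars) <- list(cols_a, cols_b)
  symmetric <- identical(sort(cols_a), sort(cols_b))
  if (symmetric && identical(cols_a, cols_b)) {
    diag(phi) <- 1
    diag(p) <- NA_real_
    diag(stars) <- ""
  }
  flagged <- sel[colSums(sub) %in% c(0L, nrow(m))]
  structure(list(phi = phi, p = p, stars = stars, flagged = flagged),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat("<phi_result> ", nrow(x$phi), " x ", ncol(x$phi),
      " phi matrix; ", sum(x$stars == "*", na.rm = TRUE),
      " pair(s) with p < 0.05\n", sep = "")
  if (length(x$flagged)) {
    cat("  zero-variance columns (phi set to 0): ",
        paste(x$flagged, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Long-format export of a phi result
#'
#' One row per column pair (upper triangle for symmetric results), ready for
#' heatmap plotting or CSV export.
#'
#' @param pr a `phi_result`.
#' @return tibble with columns `row`, `col`, `phi`, `p`, `star`.
#' @export
phi_long <- function(pr) {
  stopifnot(inherits(pr, "phi_result"))
  rn <- rownames(pr$phi); cn <- colnames(pr$phi)
  symmetric <- identical(rn, cn)
  idx <- which(if (symmetric) upper.tri(pr$phi) else
    matrix(TRUE, nrow(pr$phi), ncol(pr$phi)), arr.ind = TRUE)
  tibble::tibble(row = rn[idx[, 1]], col = cn[idx[, 2]],
                 phi = pr$phi[idx], p = pr$p[idx], star = pr$stars[idx])
}

#' Pairwise co-occurrence counts
#'
#' Counts, for every unordered pair of terms in a field, the number of
#' formulas containing both. Pairs are reported with `item_a < item_b`
#' lexicographically, filtered to `count >= min_count` and sorted by count
#' descending.
#'
#' @param ds a `formula_dataset`.
#' @param field `"ingredient"` or an annotation field.
#' @param min_count minimum co-occurrence count to report (default 1).
#' @return tibble with columns `item_a`, `item_b`, `count`.
#' @export
cooc <- function(ds, field = "ingredient", min_count = 1L) {
  stopifnot(inherits(ds, "formula_dataset"))
  if (min_count < 0L) stop("min_count must be >= 0", call. = FALSE)
  if (field == "ingredient") {
    sets <- ds$formulas
  } else {
    ann <- ds$annotations
    if (is.null(ann) || !field %in% names(ann)) {
      stop("unknown or absent field: ", field, call. = FALSE)
    }
    sets <- strsplit(ann[[field]][!is.na(ann[[field]])], "|", fixed = TRUE)
  }
  items <- sort(unique(unlist(sets)))
  if (length(items) < 2L || length(sets) == 0L) {
    return(tibble::tibble(item_a = character(), item_b = character(),
                          count = integer()))
  }
  inc <- vapply(items, function(it)
    vapply(sets, function(s) it %in% s, logical(1)), logical(length(sets)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = 1L)
  cross <- crossprod(inc * 1L)
  idx <- which(upper.tri(cross), arr.ind = TRUE)
  out <- tibble::tibble(item_a = items[idx[, 1]], item_b = items[idx[, 2]],
                        count = as.integer(cross[idx]))
  out <- out[out$count >= min_count, ]
  out[order(-out$count, out$item_a, out$item_b), ]
}

#' Co-occurrence network export
#'
#' Builds a weighted undirected graph from a co-occurrence table: nodes are
#' the items appearing in retained edges (with their formula-frequency as a
#' node attribute), edge weights are co-occurrence counts.
#'
#' @param ct co-occurrence table from [cooc()].
#' @param freq frequency table from [freq_table()] supplying the node
#'   `frequency` attribute.
#' @param min_count keep edges with `count >= min_count`.
#' @return an [igraph::graph] object.
#' @export
cooc_network <- function(ct, freq, min_count = 1L) {
  ed <- ct[ct$count >= min_count, ]
  if (nrow(ed) == 0L) {
    stop("no co-occurrence edge reaches min_count = ", min_count,
         call. = FALSE)
  }
  nodes <- sort(unique(c(ed$item_a, ed$item_b)))
  fr <- stats::setNames(freq$count, freq$term)[nodes]
  igraph::graph_from_data_frame(
    data.frame(from = ed$item_a, to = ed$item_b, weight = ed$count),
    directed = FALSE,
    vertices = data.frame(name = nodes, frequency = as.integer(fr))
  )
}
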