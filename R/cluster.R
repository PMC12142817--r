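#' Item dissimilarity from a binary occurrence matrix
#'
#' Two metrics over the occurrence profiles of items (columns):
#' `jaccard_binary`, d = 1 - |intersection| / |union| of the formula sets
#' containing each item; and `one_minus_phi`, d = 1 - phi coefficient,
#' clipped to \[0, 2\]. Items that never occur have no defined profile and
#' raise an error naming them.
#'
#' @param m binary matrix (formulas x items), e.g. from [to_wide()].
#' @param metric `"jaccard_binary"` or `"one_minus_phi"`.
#' @return symmetric dissimilarity matrix with a `metric` attribute.
#' @export
compute_distance <- function(m, metric = c("jaccard_binary",
                                           "one_minus_phi")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 items", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("matrix must be binary", call. = FALSE)
  never <- colnames(m)[colSums(m) == 0]
  if (length(never)) {
    stop("item(s) never occurring: ", paste(never, collapse = ", "),
         call. = FALSE)
  }
  if (metric == "jaccard_binary") {
    inter <- crossprod(m)
    sizes <- diag(inter)
    union <- outer(sizes, sizes, "+") - inter
    d <- 1 - inter / union
  } else {
    d <- 1 - calc_phi(m, colnames(m), colnames(m))$phi
    d <- pmin(pmax(d, 0), 2)
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  attr(d, "metric") <- metric
  d
}

seven_linkages <- c("ward.D", "ward.D2", "single", "complete", "average",
                    "centroid", "median")

#' Agglomerative clustering under a named linkage
#'
#' Lance-Williams agglomeration of a dissimilarity matrix under one of the
#' seven standard linkages (`ward.D`, `ward.D2`, `single`, `complete`,
#' `average`, `centroid`, `median`), delegating to [stats::hclust()] with
#' exactly those method tags. `ward.D` applies Ward's update to the raw
#' dissimilarities, `ward.D2` to their squares (heights returned on the
#' original scale); `centroid` and `median` can produce height inversions,
#' which is expected behavior for those linkages.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param linkage one of the seven linkage tags.
#' @return an [stats::hclust] object.
#' @export
agglomerate <- function(d, linkage = seven_linkages) {
  linkage <- match.arg(linkage, choices = seven_linkages)
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Merge table of a dendrogram
#'
#' Flat, plot-ready export of an hclust merge history: one row per merge with
#' the two joined clusters (negative = leaf index, per hclust convention) and
#' the merge height.
#'
#' @param h an `hclust` object.
#' @return tibble with columns `step`, `cluster_a`, `cluster_b`, `height`.
#' @export
merge_table <- function(h) {
  tibble::tibble(step = seq_len(nrow(h$merge)),
                 cluster_a = h$merge[, 1], cluster_b = h$merge[, 2],
                 height = h$height)
}

#' Preliminary clustering-structure survey under all seven linkages
#'
#' Runs [agglomerate()] for each of the seven linkages, returning the seven
#' dendrograms plus a summary of merge-height ranges so the structures can
#' be compared before committing to one method.
#'
#' @param d symmetric dissimilarity matrix.
#' @return list of class `cluster_survey`: `dendrograms` (named list of
#'   `hclust` objects) and `summary` (tibble with height range and
#'   agglomerative-coefficient-style statistics per linkage).
#' @export
explore_cluster <- function(d) {
  dens <- lapply(seven_linkages, function(l) agglomerate(d, l))
  names(dens) <- seven_linkages
  summ <- dplyr::bind_rows(lapply(seven_linkages, function(l) {
    h <- dens[[l]]
    tibble::tibble(linkage = l, n_merges = length(h$height),
                   height_min = min(h$height), height_max = max(h$height),
                   monotone = !is.unsorted(h$height))
  }))
  structure(list(dendrograms = dens, summary = summ),
            class = "cluster_survey")
}

#' @export
print.cluster_survey <- function(x, ...) {
  cat("<cluster_survey> seven linkages over",
      length(x$dendrograms[[1]]$labels), "items\n")
  print(x$summary)
  invisible(x)
}
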