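#' Jaccard coefficient of two ingredient sets
#'
#' J(A, B) = |A intersect B| / |A union B|. Symmetric, bounded in \[0, 1\],
#' and equal to 1 exactly when the two (non-empty) sets are identical.
#'
#' @param a,b character vectors of standardized terms (treated as sets); not
#'   both empty.
#' @return the coefficient.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("both sets are empty", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity of all formulas in a dataset
#'
#' Returns both the full symmetric Jaccard matrix over formula ids and a
#' pair table of the formula pairs at or above the threshold, sorted by
#' coefficient descending. The pair table is the direct input for a formula
#' similarity network.
#'
#' @param ds a `formula_dataset` with at least 2 formulas.
#' @param threshold minimum coefficient for the pair table (inclusive,
#'   default 0).
#' @return list of class `jaccard_result`: `matrix` and `pair_table`
#'   (`id_a`, `id_b`, `jaccard`).
#' @export
calc_jaccard <- function(ds, threshold = 0) {
  stopifnot(inherits(ds, "formula_dataset"))
  if (n_formulas(ds) < 2L) stop("need at least 2 formulas", call. = FALSE)
  m <- to_wide(ds)
  inter <- tcrossprod(m)
  sizes <- diag(inter)
  union <- outer(sizes, sizes, "+") - inter
  jm <- inter / union
  jm[union == 0] <- NA_real_   # two empty formulas (only if keep_empty)
  diag(jm) <- 1
  idx <- which(upper.tri(jm), arr.ind = TRUE)
  pt <- tibble::tibble(id_a = rownames(jm)[idx[, 1]],
                       id_b = rownames(jm)[idx[, 2]],
                       jaccard = jm[idx])
  pt <- pt[!is.na(pt$jaccard) & pt$jaccard >= threshold, ]
  pt <- pt[order(-pt$jaccard, pt$id_a, pt$id_b), ]
  structure(list(matrix = jm, pair_table = pt, threshold = threshold),
            class = "jaccard_result")
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat("<jaccard_result> ", nrow(x$matrix), " formulas; ",
      nrow(x$pair_table), " pair(s) with J >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Similarity score between two formula groups
#'
#' The mean Jaccard coefficient over all n x m cross pairs of the two
#' groups:
#' \deqn{\mathrm{grpSimScore} = \frac{1}{n \times m}
#'   \sum_{i=1}^{n}\sum_{j=1}^{m} J(A_i, B_j)}
#' Used to compare prescription groups across lineages, dynasties or
#' regions. Symmetric in its arguments; equals 1 iff every cross pair is
#' identical.
#'
#' @param group_a,group_b `formula_dataset`s (or named lists of ingredient
#'   sets); both non-empty.
#' @return the score, in \[0, 1\].
#' @export
grp_sim_score <- function(group_a, group_b) {
  ga <- if (inherits(group_a, "formula_dataset")) group_a$formulas else group_a
  gb <- if (inherits(group_b, "formula_dataset")) group_b$formulas else group_b
  if (length(ga) == 0L || length(gb) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  s <- 0
  for (a in ga) for (b in gb) s <- s + jaccard(a, b)
  s / (length(ga) * length(gb))
}

#' Role weights for weighted formula similarity
#'
#' The classical jun-chen-zuo-shi roles rank ingredients by importance
#' within a formula: Monarch (the principal herb), Minister, Assistant,
#' Envoy. Herbs outside the core formula take the `unassigned` weight.
#'
#' @param monarch,minister,assistant,envoy,unassigned positive weights
#'   (defaults 4, 3, 2, 1, 1).
#' @return named numeric vector of class `role_weights`.
#' @export
role_weights <- function(monarch = 4, minister = 3, assistant = 2,
                         envoy = 1, unassigned = 1) {
  w <- c(Monarch = monarch, Minister = minister, Assistant = assistant,
         Envoy = envoy, unassigned = unassigned)
  if (any(w <= 0)) stop("all role weights must be positive", call. = FALSE)
  structure(w, class = c("role_weights", "numeric"))
}

#' Role-weighted similarity to a core formula
#'
#' A weighted Jaccard coefficient between a core formula — whose herbs carry
#' Monarch/Minister/Assistant/Envoy role assignments — and every formula of
#' a dataset:
#' \deqn{score(F) = \frac{\sum_{h \in core \cap F} w(role(h))}
#'   {\sum_{h \in core \cup F} w(role(h))}}
#' where herbs outside the core take the `unassigned` weight. With all
#' weights equal this reduces exactly to the plain Jaccard coefficient.
#'
#' @param core named character vector: names are the core herbs, values
#'   their roles (`"Monarch"`, `"Minister"`, `"Assistant"`, `"Envoy"`).
#'   Every core herb must carry a role.
#' @param others a `formula_dataset` of formulas to score.
#' @param w a [role_weights()] vector.
#' @return tibble (`formula_id`, `weighted_score`), sorted descending.
#' @export
wt_similarity <- function(core, others, w = role_weights()) {
  stopifnot(inherits(others, "formula_dataset"))
  if (is.null(names(core)) || any(!nzchar(names(core)))) {
    stop("core must be a named vector: names = herbs, values = roles",
         call. = FALSE)
  }
  roles <- as.character(core)
  herbs <- names(core)
  bad <- !roles %in% c("Monarch", "Minister", "Assistant", "Envoy")
  if (any(bad)) {
    stop("core herb(s) without a valid role assignment: ",
         paste(herbs[bad], collapse = ", "), call. = FALSE)
  }
  core_w <- stats::setNames(unclass(w)[roles], herbs)
  scores <- vapply(others$formulas, function(f) {
    inter <- intersect(herbs, f)
    uni <- union(herbs, f)
    wsum <- function(h) sum(ifelse(h %in% herbs, core_w[h],
                                   unclass(w)[["unassigned"]]))
    denom <- wsum(uni)
    if (denom == 0) return(0)
    wsum(inter) / denom
  }, double(1))
  out <- tibble::tibble(formula_id = names(others$formulas),
                        weighted_score = unname(scores))
  out[order(-out$weighted_score, out$formula_id), ]
}

#' Find formulas similar to a target
#'
#' Scans a reference dataset (e.g. the classical formula collection) for
#' formulas whose Jaccard similarity to the target composition reaches the
#' threshold, ranked descending with formula-id tie-break, truncated to
#' `top_k`.
#'
#' @param target character vector: the target ingredient set (non-empty).
#' @param reference a non-empty `formula_dataset`.
#' @param threshold minimum Jaccard coefficient (inclusive; default 0).
#' @param top_k maximum number of hits (default all).
#' @return tibble (`formula_id`, `jaccard`), ranked.
#' @export
find_sim_rxs <- function(target, reference, threshold = 0, top_k = Inf) {
  stopifnot(inherits(reference, "formula_dataset"))
  if (length(target) == 0L) stop("target set is empty", call. = FALSE)
  if (n_formulas(reference) == 0L) {
    stop("reference dataset is empty", call. = FALSE)
  }
  j <- vapply(reference$formulas, function(f) jaccard(target, f), double(1))
  out <- tibble::tibble(formula_id = names(reference$formulas),
                        jaccard = unname(j))
  out <- out[out$jaccard >= threshold, ]
  out <- out[order(-out$jaccard, out$formula_id), ]
  utils::head(out, n = top_k)
}

#' Thresholded formula similarity network with degree centrality
#'
#' Keeps the formula pairs with Jaccard coefficient *strictly above* the
#' threshold (the conventional cut is 0.8 for highly similar
#' prescriptions), builds the undirected network, and computes each node's
#' degree centrality — incident edges divided by (number of nodes - 1);
#' higher degree marks a formula central to its group. Node sizes in the
#' usual rendering map to occurrence frequency, carried here as a node
#' attribute. Formulas isolated at the threshold are excluded.
#'
#' @param jr a `jaccard_result` from [calc_jaccard()].
#' @param freq optional named vector (or `freq_table()`-like tibble with
#'   `term`/`count`) of per-formula occurrence counts for the node
#'   `frequency` attribute; defaults to 1.
#' @param threshold edge cut, in \[0, 1): keep J > threshold.
#' @return an [igraph::graph]; vertex attributes `frequency` and
#'   `degree_centrality`, edge attribute `jaccard`.
#' @export
similarity_network <- function(jr, freq = NULL, threshold = 0.8) {
  stopifnot(inherits(jr, "jaccard_result"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  jm <- jr$matrix
  idx <- which(upper.tri(jm) & jm > threshold & !is.na(jm), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("no formula pair exceeds threshold ", threshold, call. = FALSE)
  }
  ed <- data.frame(from = rownames(jm)[idx[, 1]],
                   to = rownames(jm)[idx[, 2]],
                   jaccard = jm[idx])
  nodes <- sort(unique(c(ed$from, ed$to)))
  fr <- rep(1, length(nodes))
  if (!is.null(freq)) {
    fv <- if (is.data.frame(freq)) stats::setNames(freq$count, freq$term)
          else freq
    fr <- ifelse(nodes %in% names(fv), fv[nodes], 1)
  }
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = nodes, frequency = as.numeric(fr)))
  dc <- igraph::degree(g) / (length(nodes) - 1)
  igraph::V(g)$degree_centrality <- unname(dc)
  g
}

#' Node and edge tables of a similarity or co-occurrence network
#'
#' Tidy export for plotting or CSV writing.
#'
#' @param g an [igraph::graph].
#' @return list of tibbles `nodes` (all vertex attributes) and `edges`
#'   (endpoints plus edge attributes).
#' @export
network_tables <- function(g) {
  list(nodes = tibble::as_tibble(igraph::as_data_frame(g, what = "vertices")),
       edges = tibble::as_tibble(igraph::as_data_frame(g, what = "edges")))
}
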