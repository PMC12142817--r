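#' Convert a formula dataset into a transaction set
#'
#' Each prescription becomes one transaction over the universe of
#' standardized ingredient labels; this is the input form of the
#' association-rule miner.
#'
#' @param ds a `formula_dataset` (or a binary wide matrix).
#' @return object of class `transaction_set`: list of item-index vectors
#'   plus the item universe.
#' @export
trans_rules <- function(ds) {
  if (is.matrix(ds)) ds <- to_long(ds)
  stopifnot(inherits(ds, "formula_dataset"))
  items <- sort(unique(unlist(ds$formulas)))
  tr <- lapply(ds$formulas, function(s) sort(match(s, items)))
  structure(list(transactions = tr, items = items), class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set> ", length(x$transactions), " transactions over ",
      length(x$items), " items\n", sep = "")
  invisible(x)
}

# itemsets encoded as sorted integer vectors; key = collapsed string
iset_key <- function(s) paste(s, collapse = " ")

# count support of candidate itemsets against a transactions-x-items
# incidence matrix
count_itemsets <- function(cands, inc) {
  vapply(cands, function(s) {
    if (length(s) == 1L) sum(inc[, s]) else sum(rowSums(inc[, s, drop = FALSE]) == length(s))
  }, double(1))
}

# Apriori candidate generation: join frequent (k-1)-itemsets sharing a
# (k-2)-prefix, then prune candidates with an infrequent (k-1)-subset
apriori_gen <- function(freq_k1) {
  if (length(freq_k1) < 2L) return(list())
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (s in freq_k1) assign(iset_key(s), TRUE, envir = keys)
  k1 <- length(freq_k1[[1]])
  prefixes <- vapply(freq_k1, function(s) iset_key(s[-k1]), character(1))
  cands <- list()
  for (pref in unique(prefixes)) {
    grp <- freq_k1[prefixes == pref]
    if (length(grp) < 2L) next
    lasts <- sort(vapply(grp, function(s) s[k1], integer(1)))
    base <- grp[[1]][-k1]
    for (i in seq_len(length(lasts) - 1L)) {
      for (j in (i + 1L):length(lasts)) {
        cand <- c(base, lasts[i], lasts[j])
        # prune: all (k-1)-subsets must be frequent
        ok <- all(vapply(seq_along(cand), function(d) {
          exists(iset_key(cand[-d]), envir = keys, inherits = FALSE)
        }, logical(1)))
        if (ok) cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  cands
}

#' Mine frequent itemsets (Apriori)
#'
#' Level-wise Apriori search: exactly the itemsets of size >= 1 whose support
#' (fraction of transactions containing all items) reaches `min_support`.
#' Downward closure holds by construction.
#'
#' @param t a `transaction_set` (or a `formula_dataset`, converted via
#'   [trans_rules()]).
#' @param min_support minimum support, in (0, 1].
#' @param max_len maximum itemset size (default 5; bounds combinatorial
#'   blowup on dense herbal data).
#' @return tibble with columns `itemset` (items `|`-joined, alphabetical),
#'   `size`, `support`, `count`, sorted by support descending then itemset.
#' @export
mine_frequent_itemsets <- function(t, min_support, max_len = 5L) {
  if (inherits(t, "formula_dataset")) t <- trans_rules(t)
  stopifnot(inherits(t, "transaction_set"))
  if (length(t$transactions) == 0L) {
    stop("transaction set is empty", call. = FALSE)
  }
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]", call. = FALSE)
  }
  n <- length(t$transactions)
  p <- length(t$items)
  inc <- matrix(0L, n, p)
  for (i in seq_len(n)) inc[i, t$transactions[[i]]] <- 1L
  min_count <- min_support * n - 1e-9   # support >= min_support, no FP slop
  level <- lapply(which(colSums(inc) >= min_count), function(i) i)
  all_sets <- list(); all_counts <- double()
  k <- 1L
  while (length(level) && k <= max_len) {
    counts <- count_itemsets(level, inc)
    keep <- counts >= min_count
    level <- level[keep]; counts <- counts[keep]
    all_sets <- c(all_sets, level)
    all_counts <- c(all_counts, counts)
    k <- k + 1L
    if (k > max_len) break
    level <- apriori_gen(level)
    if (length(level)) {
      counts <- count_itemsets(level, inc)
      level <- level[counts >= min_count]
    }
  }
  if (length(all_sets) == 0L) {
    return(tibble::tibble(itemset = character(), size = integer(),
                          support = double(), count = integer()))
  }
  out <- tibble::tibble(
    itemset = vapply(all_sets, function(s)
      paste(t$items[s], collapse = "|"), character(1)),
    size = lengths(all_sets),
    support = all_counts / n,
    count = as.integer(round(all_counts))
  )
  out[order(-out$support, out$itemset), ]
}

#' Extract association rules
#'
#' Enumerates rules antecedent -> consequent from the frequent itemsets,
#' keeping those meeting the support and confidence thresholds. By default
#' consequents are single items (one rule per frequent itemset and
#' consequent item); multi-item consequents are available via
#' `multi_consequent = TRUE`. With `retain_lift_gt1 = TRUE` only rules with
#' lift strictly greater than 1 — positively associated combinations — are
#' kept.
#'
#' @param t a `transaction_set` or `formula_dataset`.
#' @param min_support minimum rule support, in (0, 1].
#' @param min_confidence minimum confidence, in (0, 1].
#' @param retain_lift_gt1 keep only rules with lift > 1 (strict).
#' @param max_len maximum size of antecedent plus consequent (>= 2).
#' @param multi_consequent also enumerate consequents with more than one
#'   item.
#' @return tibble of class `rule_set` with columns `antecedent`,
#'   `consequent` (items `|`-joined), `support`, `confidence`, `lift`,
#'   `count`, deterministically sorted by lift desc, support desc, then
#'   antecedent/consequent.
#' @export
extract_rules <- function(t, min_support, min_confidence,
                          retain_lift_gt1 = FALSE, max_len = 5L,
                          multi_consequent = FALSE) {
  if (inherits(t, "formula_dataset")) t <- trans_rules(t)
  stopifnot(inherits(t, "transaction_set"))
  if (min_confidence <= 0 || min_confidence > 1) {
    stop("min_confidence must be in (0, 1]", call. = FALSE)
  }
  if (max_len < 2L) stop("max_len must be >= 2", call. = FALSE)
  fi <- mine_frequent_itemsets(t, min_support, max_len = max_len)
  supp <- stats::setNames(fi$support, fi$itemset)
  cnt <- stats::setNames(fi$count, fi$itemset)
  big <- fi[fi$size >= 2L, ]
  rows <- vector("list", 0L)
  for (r in seq_len(nrow(big))) {
    items <- strsplit(big$itemset[r], "|", fixed = TRUE)[[1]]
    k <- length(items)
    cons_sizes <- if (multi_consequent) seq_len(k - 1L) else 1L
    for (cs in cons_sizes) {
      combs <- utils::combn(k, cs, simplify = FALSE)
      for (ci in combs) {
        cons <- items[ci]; ante <- items[-ci]
        a_key <- paste(ante, collapse = "|")
        c_key <- paste(cons, collapse = "|")
        sa <- unname(supp[a_key]); sc <- unname(supp[c_key])
        if (is.na(sa) || is.na(sc)) next  # cannot happen: downward closure
        conf <- big$support[r] / sa
        if (conf < min_confidence - 1e-12) next
        lift <- conf / sc
        if (retain_lift_gt1 && lift <= 1) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          antecedent = a_key, consequent = c_key,
          support = big$support[r], confidence = conf, lift = lift,
          count = cnt[[big$itemset[r]]]
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(antecedent = character(), consequent = character(),
                   support = double(), confidence = double(),
                   lift = double(), count = integer())
  }
  out <- out[order(-out$lift, -out$support, out$antecedent, out$consequent), ]
  class(out) <- c("rule_set", class(out))
  out
}

#' Batch exploration of the rule-parameter grid
#'
#' Evaluates [extract_rules()] at every combination of the supplied minimum
#' supports and confidences (|supports| x |confidences| evaluations) with
#' lift > 1 retention, and summarizes each: number of rules, support range,
#' confidence range, minimum lift. Combinations yielding no rules — whose
#' range statistics would be undefined (the infinite-range cases produced by
#' excessively high or low parameter settings) — are removed from the
#' returned table; the complete grid, including empty combinations with
#' `n_rules = 0`, is kept in the `full_grid` attribute for bubble-chart
#' style export.
#'
#' @param t a `transaction_set` or `formula_dataset`.
#' @param supports non-empty vector of minimum supports.
#' @param confidences non-empty vector of minimum confidences.
#' @param max_len maximum rule length (see [extract_rules()]).
#' @return tibble with one row per surviving combination: `min_support`,
#'   `min_confidence`, `n_rules`, `support_min`, `support_max`,
#'   `confidence_min`, `confidence_max`, `min_lift`; attribute `full_grid`
#'   holds all combinations.
#' @export
explore_rules <- function(t, supports, confidences, max_len = 5L) {
  if (inherits(t, "formula_dataset")) t <- trans_rules(t)
  if (length(supports) == 0L || length(confidences) == 0L) {
    stop("supports and confidences must be non-empty", call. = FALSE)
  }
  supports <- sort(unique(supports)); confidences <- sort(unique(confidences))
  # mine once at the loosest thresholds; each grid cell is a filter of that
  # rule set, which is exactly equivalent to re-mining per cell
  base <- extract_rules(t, min_support = min(supports),
                        min_confidence = min(confidences),
                        retain_lift_gt1 = TRUE, max_len = max_len)
  grid <- expand.grid(min_support = supports, min_confidence = confidences,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$min_support[i]; c0 <- grid$min_confidence[i]
    r <- base[base$support >= s - 1e-12 & base$confidence >= c0 - 1e-12, ]
    if (nrow(r) == 0L) {
      tibble::tibble(min_support = s, min_confidence = c0, n_rules = 0L,
                     support_min = NA_real_, support_max = NA_real_,
                     confidence_min = NA_real_, confidence_max = NA_real_,
                     min_lift = NA_real_)
    } else {
      tibble::tibble(min_support = s, min_confidence = c0,
                     n_rules = nrow(r),
                     support_min = min(r$support),
                     support_max = max(r$support),
                     confidence_min = min(r$confidence),
                     confidence_max = max(r$confidence),
                     min_lift = min(r$lift))
    }
  })
  full <- dplyr::bind_rows(rows)
  out <- full[full$n_rules > 0L, ]
  attr(out, "full_grid") <- full
  out
}

#' Bipartite item-rule network of an association rule set
#'
#' Builds the graph export behind rule-network plots: one node per item, one
#' node per rule, and directed edges antecedent item -> rule -> consequent
#' item. Rule nodes carry support, confidence and lift attributes.
#'
#' @param rules a `rule_set` from [extract_rules()].
#' @return an [igraph::graph] object; vertex attribute `type` is `"item"` or
#'   `"rule"`.
#' @export
rules_network <- function(rules) {
  if (nrow(rules) == 0L) stop("empty rule set", call. = FALSE)
  rule_ids <- paste0("rule_", seq_len(nrow(rules)))
  edges <- lapply(seq_len(nrow(rules)), function(i) {
    ante <- strsplit(rules$antecedent[i], "|", fixed = TRUE)[[1]]
    cons <- strsplit(rules$consequent[i], "|", fixed = TRUE)[[1]]
    rbind(cbind(ante, rule_ids[i]), cbind(rule_ids[i], cons))
  })
  edges <- do.call(rbind, edges)
  items <- sort(unique(c(unlist(strsplit(rules$antecedent, "|", fixed = TRUE)),
                         unlist(strsplit(rules$consequent, "|", fixed = TRUE)))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE,
    vertices = data.frame(
      name = c(items, rule_ids),
      type = c(rep("item", length(items)), rep("rule", length(rule_ids))),
      support = c(rep(NA_real_, length(items)), rules$support),
      confidence = c(rep(NA_real_, length(items)), rules$confidence),
      lift = c(rep(NA_real_, length(items)), rules$lift)
    )
  )
  g
}
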