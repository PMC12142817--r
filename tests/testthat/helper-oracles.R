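# Independent brute-force oracles. These deliberately share no code with the
# package: itemsets by exhaustive subset enumeration, agglomeration by a
# naive Lance-Williams loop, similarity by direct set arithmetic.

# all frequent itemsets by enumerating every subset of the item universe
bf_frequent <- function(transactions, min_support, max_len = 5L) {
  items <- sort(unique(unlist(transactions)))
  n <- length(transactions)
  out <- list()
  for (k in seq_len(min(length(items), max_len))) {
    for (comb in utils::combn(items, k, simplify = FALSE)) {
      cnt <- sum(vapply(transactions, function(tr) all(comb %in% tr),
                        logical(1)))
      if (cnt / n >= min_support - 1e-12) {
        out[[paste(comb, collapse = "|")]] <- cnt / n
      }
    }
  }
  out
}

# all rules with singleton consequents from brute-force frequent itemsets
bf_rules <- function(transactions, min_support, min_confidence,
                     lift_gt1 = FALSE, max_len = 5L) {
  n <- length(transactions)
  supp_of <- function(set) {
    sum(vapply(transactions, function(tr) all(set %in% tr), logical(1))) / n
  }
  fi <- bf_frequent(transactions, min_support, max_len)
  rows <- list()
  for (key in names(fi)) {
    set <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(set) < 2L) next
    for (cons in set) {
      ante <- setdiff(set, cons)
      conf <- fi[[key]] / supp_of(ante)
      if (conf < min_confidence - 1e-12) next
      lift <- conf / supp_of(cons)
      if (lift_gt1 && lift <= 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        antecedent = paste(sort(ante), collapse = "|"), consequent = cons,
        support = fi[[key]], confidence = conf, lift = lift)
    }
  }
  if (!length(rows)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = double(), confidence = double(),
                      lift = double()))
  }
  out <- do.call(rbind, rows)
  out[order(out$antecedent, out$consequent), ]
}

# reference Lance-Williams agglomeration; returns merge heights in order
lw_heights <- function(d, method) {
  D <- as.matrix(d)
  if (method == "ward.D2") D <- D^2
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bmin <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        v <- D[active[ii], active[jj]]
        if (v < bmin) { bmin <- v; best <- c(active[ii], active[jj]) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bmin
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      co <- switch(method,
        single   = c(0.5, 0.5, 0, -0.5),
        complete = c(0.5, 0.5, 0, 0.5),
        average  = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
        ward.D   = ,
        ward.D2  = c((ni + nk) / (ni + nj + nk), (nj + nk) / (ni + nj + nk),
                     -nk / (ni + nj + nk), 0),
        centroid = c(ni / (ni + nj), nj / (ni + nj),
                     -ni * nj / (ni + nj)^2, 0),
        median   = c(0.5, 0.5, -0.25, 0))
      D[i, k] <- D[k, i] <- co[1] * D[i, k] + co[2] * D[j, k] +
        co[3] * D[i, j] + co[4] * abs(D[i, k] - D[j, k])
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  if (method == "ward.D2") heights <- sqrt(heights)
  heights
}

# direct 2x2-table phi via Pearson correlation of expanded binary vectors
bf_phi_from_counts <- function(a, b, c0, d0) {
  x <- c(rep(1, a + b), rep(0, c0 + d0))
  y <- c(rep(1, a), rep(0, b), rep(1, c0), rep(0, d0))
  suppressWarnings(stats::cor(x, y))
}

bf_jaccard <- function(a, b) {
  length(intersect(unique(a), unique(b))) / length(union(a, b))
}

# random transaction set over a small alphabet
random_transactions <- function(n_tr, n_items, rng_items = 1:4) {
  alphabet <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_tr), function(i) {
    size <- min(sample(rng_items, 1), length(alphabet))
    sort(sample(alphabet, size))
  })
}

random_dataset <- function(n_formulas, n_items, size_range = 2:5) {
  alphabet <- paste0("h", seq_len(n_items))
  sets <- lapply(seq_len(n_formulas), function(i)
    sort(sample(alphabet, sample(size_range, 1))))
  names(sets) <- sprintf("F%03d", seq_len(n_formulas))
  formula_dataset(sets)
}
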