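# Internal validity indices over a dissimilarity matrix and a hard partition.
# Each index function returns a scalar; `direction` says whether the best k
# maximizes or minimizes it. All are distance-based formulations so they can
# be evaluated on any dissimilarity (Jaccard, 1 - phi, ...), using medoids
# where the classical definition needs centroids.

pair_split <- function(d, cl) {
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  dist_v <- d[upper.tri(d)]
  within <- cl[idx[, 1]] == cl[idx[, 2]]
  list(dist = dist_v, within = within)
}

medoids <- function(d, cl) {
  vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    if (length(members) == 1L) return(members)
    members[which.min(rowSums(d[members, members, drop = FALSE]))]
  }, integer(1))
}

# total/within dispersion via the pairwise squared-distance identity
within_dispersion <- function(d, cl) {
  sum(vapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    if (length(members) < 2L) return(0)
    dd <- d[members, members]
    sum(dd[upper.tri(dd)]^2) / length(members)
  }, double(1)))
}

idx_silhouette <- function(d, cl) {
  if (length(unique(cl)) < 2L) return(NA_real_)
  mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
}

idx_calinski_harabasz <- function(d, cl) {
  n <- nrow(d); k <- length(unique(cl))
  tot <- sum(d[upper.tri(d)]^2) / n
  w <- within_dispersion(d, cl)
  b <- tot - w
  if (w <= 0 || k < 2L || k >= n) return(NA_real_)
  (b / (k - 1)) / (w / (n - k))
}

idx_davies_bouldin <- function(d, cl) {
  ks <- sort(unique(cl))
  if (length(ks) < 2L) return(NA_real_)
  med <- medoids(d, cl)
  scatter <- vapply(seq_along(ks), function(i) {
    members <- which(cl == ks[i])
    mean(d[members, med[i]])
  }, double(1))
  db <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      sep <- d[med[i], med[j]]
      if (sep == 0) return(Inf)
      (scatter[i] + scatter[j]) / sep
    }, double(1)))
  }, double(1))
  mean(db)
}

idx_dunn <- function(d, cl) {
  ps <- pair_split(d, cl)
  if (!any(ps$within) || !any(!ps$within)) return(NA_real_)
  diam <- max(ps$dist[ps$within])
  if (diam == 0) return(NA_real_)
  min(ps$dist[!ps$within]) / diam
}

idx_c_index <- function(d, cl) {
  ps <- pair_split(d, cl)
  nw <- sum(ps$within)
  if (nw == 0L) return(NA_real_)
  s <- sum(ps$dist[ps$within])
  sorted <- sort(ps$dist)
  s_min <- sum(sorted[seq_len(nw)])
  s_max <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (s_max == s_min) return(NA_real_)
  (s - s_min) / (s_max - s_min)
}

idx_mcclain_rao <- function(d, cl) {
  ps <- pair_split(d, cl)
  nw <- sum(ps$within); nb <- sum(!ps$within)
  if (nw == 0L || nb == 0L) return(NA_real_)
  mb <- mean(ps$dist[!ps$within])
  if (mb == 0) return(NA_real_)
  mean(ps$dist[ps$within]) / mb
}

idx_point_biserial <- function(d, cl) {
  ps <- pair_split(d, cl)
  nw <- sum(ps$within); nb <- sum(!ps$within); nt <- length(ps$dist)
  if (nw == 0L || nb == 0L) return(NA_real_)
  sd_all <- stats::sd(ps$dist)
  if (sd_all == 0) return(NA_real_)
  (mean(ps$dist[!ps$within]) - mean(ps$dist[ps$within])) *
    sqrt(nw * nb / nt^2) / sd_all
}

concordance_counts <- function(d, cl) {
  ps <- pair_split(d, cl)
  dw <- sort(ps$dist[ps$within]); db <- sort(ps$dist[!ps$within])
  if (!length(dw) || !length(db)) return(NULL)
  # s_plus: within < between pairs; s_minus: within > between pairs
  pos_lt <- findInterval(db, dw, left.open = TRUE)     # dw strictly < each db
  s_plus <- sum(pos_lt)
  pos_le <- findInterval(db, dw)                       # dw <= each db
  s_minus <- length(dw) * length(db) - sum(pos_le)
  list(s_plus = s_plus, s_minus = s_minus, n_t = length(ps$dist))
}

idx_gamma <- function(d, cl) {
  cc <- concordance_counts(d, cl)
  if (is.null(cc) || (cc$s_plus + cc$s_minus) == 0) return(NA_real_)
  (cc$s_plus - cc$s_minus) / (cc$s_plus + cc$s_minus)
}

idx_gplus <- function(d, cl) {
  cc <- concordance_counts(d, cl)
  if (is.null(cc)) return(NA_real_)
  2 * cc$s_minus / (cc$n_t * (cc$n_t - 1))
}

idx_xie_beni <- function(d, cl) {
  ks <- sort(unique(cl))
  if (length(ks) < 2L) return(NA_real_)
  med <- medoids(d, cl)
  compact <- sum(vapply(seq_along(ks), function(i) {
    members <- which(cl == ks[i])
    sum(d[members, med[i]]^2)
  }, double(1)))
  seps <- d[med, med][upper.tri(matrix(0, length(med), length(med)))]
  if (min(seps) == 0) return(NA_real_)
  compact / (nrow(d) * min(seps)^2)
}

# needs the underlying data matrix (per-variable between-group dispersion)
idx_ratkowsky_lance <- function(data, cl) {
  k <- length(unique(cl))
  grand <- colMeans(data)
  tss <- colSums(sweep(data, 2, grand)^2)
  bgss <- colSums(do.call(rbind, lapply(sort(unique(cl)), function(g) {
    members <- which(cl == g)
    length(members) * (colMeans(data[members, , drop = FALSE]) - grand)^2
  })))
  ok <- tss > 0
  if (!any(ok)) return(NA_real_)
  mean(sqrt(bgss[ok] / tss[ok])) / sqrt(k)
}

kvote_indices <- list(
  silhouette        = list(fn = idx_silhouette,        direction = "max"),
  calinski_harabasz = list(fn = idx_calinski_harabasz, direction = "max"),
  davies_bouldin    = list(fn = idx_davies_bouldin,    direction = "min"),
  dunn              = list(fn = idx_dunn,              direction = "max"),
  c_index           = list(fn = idx_c_index,           direction = "min"),
  mcclain_rao       = list(fn = idx_mcclain_rao,       direction = "min"),
  point_biserial    = list(fn = idx_point_biserial,    direction = "max"),
  gamma             = list(fn = idx_gamma,             direction = "max"),
  g_plus            = list(fn = idx_gplus,             direction = "min"),
  xie_beni          = list(fn = idx_xie_beni,          direction = "min"),
  elbow             = list(fn = NULL,                  direction = "special"),
  ratkowsky_lance   = list(fn = NULL,                  direction = "special")
)

#' Vote for the number of clusters with internal validity indices
#'
#' Cuts a hierarchical tree (default linkage `ward.D2`) at every k in the
#' candidate range and lets each internal validity index vote for the k it
#' scores best. The default panel of twelve indices: silhouette,
#' Calinski-Harabasz, Davies-Bouldin (minimized), Dunn, C-index (minimized),
#' McClain-Rao (minimized), point-biserial, Baker-Hubert gamma, G+
#' (minimized), Xie-Beni (minimized), a within-dispersion elbow (maximum
#' second difference), and Ratkowsky-Lance. All are distance-based
#' formulations (medoids standing in where the classical definition uses
#' centroids), so any dissimilarity metric can be voted on;
#' Ratkowsky-Lance needs the underlying binary data matrix and is skipped
#' with a message when `data` is not supplied. An index failing on a
#' degenerate partition is excluded from the tally with a warning. The
#' winner is the k with most votes; ties resolve to the smallest k
#' (parsimony).
#'
#' @param d symmetric dissimilarity matrix over items.
#' @param k_range integer vector `c(k_min, k_max)`, with
#'   `2 <= k_min < k_max < n_items`.
#' @param methods index names to use (subset of the default panel).
#' @param linkage linkage for the tree being cut (default `"ward.D2"`).
#' @param data optional binary matrix (formulas x items) enabling the
#'   Ratkowsky-Lance index; items are clustered, so its *columns* must match
#'   the labels of `d`.
#' @return list of class `k_vote`: `winner` (the recommended k), `tally`
#'   (tibble k/votes), `recommendations` (tibble method/best_k),
#'   `values` (matrix of index values, methods x k), `failed` (methods
#'   excluded).
#' @export
k_selection <- function(d, k_range, methods = names(kvote_indices),
                        linkage = "ward.D2", data = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(k_range) != 2L || k_range[1] < 2L || k_range[1] >= k_range[2] ||
      k_range[2] >= n) {
    stop("k_range must satisfy 2 <= k_min < k_max < n_items", call. = FALSE)
  }
  methods <- match.arg(methods, names(kvote_indices), several.ok = TRUE)
  ks <- seq.int(k_range[1], k_range[2])
  h <- agglomerate(d, linkage)
  parts <- lapply(ks, function(k) stats::cutree(h, k = k))
  names(parts) <- ks

  if ("ratkowsky_lance" %in% methods && is.null(data)) {
    message("ratkowsky_lance needs the binary data matrix; skipped")
    methods <- setdiff(methods, "ratkowsky_lance")
  }

  values <- matrix(NA_real_, length(methods), length(ks),
                   dimnames = list(methods, ks))
  rec <- stats::setNames(rep(NA_integer_, length(methods)), methods)
  for (m in methods) {
    if (m == "elbow") {
      # within-dispersion at k extended one step each side so the second
      # difference is defined over the whole candidate range
      ks_ext <- seq.int(max(1L, k_range[1] - 1L), min(n, k_range[2] + 1L))
      w <- vapply(ks_ext, function(k)
        within_dispersion(d, stats::cutree(h, k = k)), double(1))
      curv <- vapply(seq_along(ks), function(i) {
        pos <- match(ks[i], ks_ext)
        if (pos == 1L || pos == length(ks_ext)) return(NA_real_)
        w[pos - 1L] - 2 * w[pos] + w[pos + 1L]
      }, double(1))
      values[m, ] <- curv
      if (all(is.na(curv))) next
      rec[m] <- ks[which.max(curv)]
    } else if (m == "ratkowsky_lance") {
      if (!identical(colnames(data), rownames(d))) {
        data <- data[, rownames(d), drop = FALSE]
      }
      pts <- t(as.matrix(data))   # items as rows, formulas as variables
      vals <- vapply(seq_along(ks), function(i)
        idx_ratkowsky_lance(pts, parts[[i]]), double(1))
      values[m, ] <- vals
      if (all(is.na(vals))) next
      rec[m] <- ks[which.max(vals)]
    } else {
      def <- kvote_indices[[m]]
      vals <- vapply(seq_along(ks), function(i) def$fn(d, parts[[i]]),
                     double(1))
      values[m, ] <- vals
      if (all(is.na(vals))) next
      rec[m] <- if (def$direction == "max") ks[which.max(vals)] else
        ks[which.min(vals)]
    }
  }
  failed <- methods[is.na(rec)]
  if (length(failed)) {
    warning("index(es) failed on all partitions, excluded from tally: ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  ok <- rec[!is.na(rec)]
  tally <- tibble::tibble(k = ks,
                          votes = vapply(ks, function(k)
                            sum(ok == k), integer(1)))
  winner <- tally$k[tally$votes == max(tally$votes)][1]  # ties: smallest k
  structure(list(winner = winner, tally = tally,
                 recommendations = tibble::tibble(
                   method = names(rec), best_k = unname(rec)),
                 values = values, failed = failed),
            class = "k_vote")
}

#' @export
print.k_vote <- function(x, ...) {
  cat("<k_vote> winner k =", x$winner, "\n")
  print(x$tally)
  invisible(x)
}
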