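test_that("jaccard follows the set formula and its invariants", {
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard(character(), character()), "empty")
  set.seed(19)
  for (rep in 1:30) {
    a <- sample(letters, sample(1:8, 1))
    b <- sample(letters, sample(1:8, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
    expect_equal(jaccard(a, b) == 1, setequal(a, b))
  }
})

test_that("calc_jaccard returns the full matrix and the thresholded pair table", {
  ds <- formula_dataset(list(P1 = c("x", "y"), P2 = c("x", "y")))
  jr <- calc_jaccard(ds, threshold = 0.5)
  expect_equal(unname(jr$matrix), matrix(1, 2, 2))
  expect_equal(nrow(jr$pair_table), 1)
  disj <- formula_dataset(list(P1 = "a", P2 = "b", P3 = "c"))
  expect_equal(nrow(calc_jaccard(disj, threshold = 0.1)$pair_table), 0)
  expect_error(calc_jaccard(formula_dataset(list(P1 = "a"))), "at least 2")
  set.seed(27)
  big <- random_dataset(30, 12, size_range = 2:6)
  jm <- calc_jaccard(big)$matrix
  ids <- names(big$formulas)
  for (r in 1:10) {
    i <- sample(30, 1); j <- sample(30, 1)
    expect_equal(jm[ids[i], ids[j]],
                 bf_jaccard(big$formulas[[i]], big$formulas[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(jm, t(jm))
})

test_that("grp_sim_score is the mean over all cross pairs", {
  one <- formula_dataset(list(A1 = c("x", "y")))
  expect_equal(grp_sim_score(one, one), 1)
  ga <- formula_dataset(list(A1 = c("a", "b"), A2 = c("c", "d")))
  gb <- formula_dataset(list(B1 = c("a", "b")))
  expect_equal(grp_sim_score(ga, gb), 0.5)
  expect_error(grp_sim_score(ga, formula_dataset(list())), "non-empty")
})

test_that("grp_sim_score is symmetric, bounded, and 1 iff all cross pairs identical", {
  set.seed(33)
  for (rep in 1:10) {
    ga <- random_dataset(5, 10)
    gb <- random_dataset(7, 10)
    s <- grp_sim_score(ga, gb)
    expect_equal(s, grp_sim_score(gb, ga), tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 1)
    # brute-force double sum
    tot <- 0
    for (a in ga$formulas) for (b in gb$formulas) tot <- tot + bf_jaccard(a, b)
    expect_equal(s, tot / 35, tolerance = 1e-12)
  }
  same <- formula_dataset(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(grp_sim_score(same, same), 1)
  mixed <- formula_dataset(list(A = c("x", "y"), B = c("x", "z")))
  expect_lt(grp_sim_score(mixed, mixed), 1)
})

test_that("wt_similarity follows the weighted-Jaccard definition", {
  core <- c(M = "Monarch", m = "Minister")
  ds <- formula_dataset(list(same = c("M", "m"), half = c("M", "x"),
                             none = c("p", "q")))
  out <- wt_similarity(core, ds)
  sc <- stats::setNames(out$weighted_score, out$formula_id)
  expect_equal(unname(sc["same"]), 1)
  expect_equal(unname(sc["half"]), 4 / (4 + 3 + 1))
  expect_equal(unname(sc["none"]), 0)
  expect_error(wt_similarity(c(M = "Monarch", x = "NotARole"), ds),
               "role")
  expect_error(role_weights(monarch = 0), "positive")
})

test_that("wt_similarity with equal weights reduces exactly to jaccard", {
  set.seed(44)
  w1 <- role_weights(1, 1, 1, 1, 1)
  roles <- c("Monarch", "Minister", "Assistant", "Envoy")
  for (rep in 1:100) {
    core_herbs <- sample(letters, sample(2:6, 1))
    core <- stats::setNames(sample(roles, length(core_herbs), TRUE),
                            core_herbs)
    other <- sample(letters, sample(1:8, 1))
    ds <- formula_dataset(list(F1 = other))
    expect_equal(wt_similarity(core, ds, w1)$weighted_score,
                 jaccard(core_herbs, other), tolerance = 1e-12)
  }
})

test_that("find_sim_rxs ranks, thresholds and truncates", {
  ref <- load_fixture("classics")
  ds <- clean_dataset(ref, lookup_table(unique(ref$raw_term),
                                        unique(ref$raw_term)))
  target <- ds$formulas$sijunzitang
  hits <- find_sim_rxs(target, ds)
  expect_equal(hits$formula_id[1], "sijunzitang")
  expect_equal(hits$jaccard[1], 1)
  expect_equal(nrow(find_sim_rxs(c("zzz", "yyy"), ds, threshold = 1)), 0)
  expect_equal(nrow(find_sim_rxs(target, ds, top_k = 3)), 3)
  expect_error(find_sim_rxs(character(), ds), "empty")
  set.seed(3)
  rnd <- random_dataset(15, 10)
  scan <- find_sim_rxs(c("h1", "h2"), rnd)
  ref_j <- vapply(rnd$formulas[scan$formula_id], function(f)
    bf_jaccard(c("h1", "h2"), f), double(1))
  expect_equal(scan$jaccard, unname(ref_j), tolerance = 1e-12)
})

test_that("similarity_network applies a strict threshold and normalized degree", {
  jm <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.5, 0.9, 0.5, 1), 3,
               dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
  jr <- structure(list(matrix = jm,
                       pair_table = tibble::tibble(), threshold = 0),
                  class = "jaccard_result")
  g <- similarity_network(jr, threshold = 0.8)
  expect_equal(igraph::vcount(g), 3)
  dc <- stats::setNames(igraph::V(g)$degree_centrality,
                        igraph::V(g)$name)
  expect_equal(unname(dc[c("P1", "P2", "P3")]), c(1, 0.5, 0.5))
  # strict threshold: J = 0.9 edges are NOT kept at threshold 0.9
  expect_error(similarity_network(jr, threshold = 0.95), "threshold")
  expect_error(similarity_network(jr, threshold = 1), "0, 1")
})

test_that("raising the threshold never increases any degree centrality", {
  set.seed(66)
  ds <- random_dataset(20, 8, size_range = 2:5)
  jr <- calc_jaccard(ds)
  get_deg <- function(thr) {
    g <- tryCatch(similarity_network(jr, threshold = thr),
                  error = function(e) NULL)
    if (is.null(g)) return(numeric())
    stats::setNames(igraph::degree(g), igraph::V(g)$name)
  }
  d_lo <- get_deg(0.1); d_hi <- get_deg(0.4)
  for (id in names(d_hi)) {
    expect_lte(d_hi[[id]], d_lo[[id]])
  }
})

test_that("a planted near-duplicate hub attains maximum degree centrality", {
  set.seed(100)
  hub <- paste0("h", 1:10)
  sets <- list(HUB = hub)
  for (i in 1:5) {          # near-duplicates: drop one, add one
    s <- c(setdiff(hub, sample(hub, 1)), paste0("x", i))
    sets[[paste0("V", i)]] <- s
  }
  for (i in 1:6) sets[[paste0("R", i)]] <- paste0("y", (3 * i):(3 * i + 2))
  ds <- formula_dataset(sets)
  jr <- calc_jaccard(ds)
  g <- similarity_network(jr, threshold = 0.5)
  dc <- stats::setNames(igraph::V(g)$degree_centrality, igraph::V(g)$name)
  expect_equal(names(which.max(dc)), "HUB")
  expect_true(all(dc >= 0 & dc <= 1))
})
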