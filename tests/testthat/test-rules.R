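toy4 <- function() {
  trans_rules(formula_dataset(list(T1 = c("A", "B"), T2 = c("A", "B", "C"),
                                   T3 = c("A", "C"), T4 = "B")))
}

test_that("frequent itemsets on the 4-transaction toy set are exactly right", {
  fi <- mine_frequent_itemsets(toy4(), 0.5)
  got <- stats::setNames(fi$support, fi$itemset)
  expect_mapequal(as.list(got),
                  list(A = 0.75, B = 0.75, C = 0.5, `A|B` = 0.5,
                       `A|C` = 0.5))
  # boundary behavior
  expect_true("X" %in% mine_frequent_itemsets(
    trans_rules(formula_dataset(list(F1 = "X", F2 = c("X", "Y")))),
    1.0)$itemset)
  expect_equal(nrow(mine_frequent_itemsets(toy4(), 0.8)), 0)
  expect_error(mine_frequent_itemsets(toy4(), 0), "min_support")
  expect_error(mine_frequent_itemsets(
    trans_rules(formula_dataset(list())), 0.5), "empty")
})

test_that("downward closure holds on random transaction sets", {
  set.seed(5)
  for (rep in 1:20) {
    tr <- random_transactions(sample(5:20, 1), sample(4:8, 1))
    fi <- mine_frequent_itemsets(trans_rules(formula_dataset(
      stats::setNames(tr, paste0("F", seq_along(tr))))), 0.2)
    keys <- fi$itemset
    for (key in keys) {
      items <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (length(items) < 2) next
      for (drop in seq_along(items)) {
        expect_true(paste(items[-drop], collapse = "|") %in% keys)
      }
    }
  }
})

test_that("rule metrics follow the support/confidence/lift definitions", {
  r <- extract_rules(toy4(), 0.5, 0.5)
  ab <- r[r$antecedent == "A" & r$consequent == "B", ]
  expect_equal(ab$support, 0.5)
  expect_equal(ab$confidence, 2 / 3)
  expect_equal(ab$lift, (2 / 3) / 0.75)
  # lift 8/9 < 1 -> excluded under strict lift > 1 retention
  r2 <- extract_rules(toy4(), 0.5, 0.5, retain_lift_gt1 = TRUE)
  expect_false(any(r2$antecedent == "A" & r2$consequent == "B"))
  # boundary: lift exactly 1 is excluded (strict inequality)
  dup <- trans_rules(formula_dataset(list(T1 = c("A", "B"),
                                          T2 = c("A", "B"))))
  expect_equal(nrow(extract_rules(dup, 0.5, 0.5, retain_lift_gt1 = TRUE)), 0)
  r3 <- extract_rules(dup, 0.5, 0.5)
  expect_true(all(r3$lift == 1) && nrow(r3) == 2)
})

test_that("rules match the brute-force oracle on random transaction sets", {
  set.seed(99)
  for (rep in 1:40) {
    tr <- random_transactions(sample(5:30, 1), sample(4:10, 1))
    ts <- trans_rules(formula_dataset(stats::setNames(
      tr, paste0("F", seq_along(tr)))))
    ms <- sample(c(0.1, 0.2, 0.3), 1)
    mc <- sample(c(0.4, 0.6, 0.8), 1)
    lg <- sample(c(TRUE, FALSE), 1)
    got <- extract_rules(ts, ms, mc, retain_lift_gt1 = lg)
    got <- got[order(got$antecedent, got$consequent), ]
    ref <- bf_rules(tr, ms, mc, lift_gt1 = lg)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$antecedent, ref$antecedent)
    expect_equal(got$consequent, ref$consequent)
    expect_equal(got$support, ref$support, tolerance = 1e-12)
    expect_equal(got$confidence, ref$confidence, tolerance = 1e-12)
    expect_equal(got$lift, ref$lift, tolerance = 1e-12)
  }
})

test_that("explore_rules evaluates the full grid and filters empty cells", {
  ts <- toy4()
  grid <- explore_rules(ts, supports = c(0.25, 0.5), confidences = c(0.5, 0.9))
  full <- attr(grid, "full_grid")
  expect_equal(nrow(full), 4)
  expect_true(all(grid$n_rules > 0))
  expect_true(all(is.finite(grid$support_min)))
  expect_true(all(is.finite(grid$min_lift)))
  # single-cell grid agrees with extract_rules directly
  one <- explore_rules(ts, 0.5, 0.5)
  direct <- extract_rules(ts, 0.5, 0.5, retain_lift_gt1 = TRUE)
  expect_equal(attr(one, "full_grid")$n_rules[1], nrow(direct))
  # a support no itemset reaches leaves that column out of the filtered table
  hi <- explore_rules(ts, supports = c(0.25, 0.95), confidences = 0.5)
  expect_false(0.95 %in% hi$min_support)
  expect_true(0.95 %in% attr(hi, "full_grid")$min_support)
  expect_error(explore_rules(ts, numeric(), 0.5), "non-empty")
})

test_that("grid rule counts are monotone non-increasing in both thresholds", {
  set.seed(17)
  ds <- random_dataset(40, 8, size_range = 2:6)
  grid <- attr(explore_rules(ds, supports = c(0.05, 0.1, 0.2, 0.3),
                             confidences = c(0.3, 0.5, 0.7)), "full_grid")
  for (cf in unique(grid$min_confidence)) {
    col <- grid[grid$min_confidence == cf, ]
    col <- col[order(col$min_support), ]
    expect_true(all(diff(col$n_rules) <= 0))
  }
  for (s in unique(grid$min_support)) {
    row <- grid[grid$min_support == s, ]
    row <- row[order(row$min_confidence), ]
    expect_true(all(diff(row$n_rules) <= 0))
  }
})

test_that("rules_network builds the bipartite item-rule graph", {
  ds <- formula_dataset(list(T1 = c("A", "B"), T2 = c("A", "B")))
  r <- extract_rules(ds, 0.5, 0.5)
  g <- rules_network(r[1, ])
  expect_equal(igraph::vcount(g), 3)   # A, rule, B
  expect_equal(igraph::ecount(g), 2)
  g2 <- rules_network(r)               # two rules sharing both items
  expect_equal(sum(igraph::V(g2)$type == "item"), 2)
  expect_equal(sum(igraph::V(g2)$type == "rule"), 2)
  expect_error(rules_network(r[0, ]), "empty")
})

test_that("rule network node/edge counts match direct construction on a bigger set", {
  set.seed(31)
  ds <- random_dataset(60, 8, size_range = 2:6)
  r <- extract_rules(ds, 0.05, 0.3)
  r <- utils::head(r, 20)
  g <- rules_network(r)
  items <- unique(c(unlist(strsplit(r$antecedent, "|", fixed = TRUE)),
                    unlist(strsplit(r$consequent, "|", fixed = TRUE))))
  n_edges <- sum(lengths(strsplit(r$antecedent, "|", fixed = TRUE))) +
    sum(lengths(strsplit(r$consequent, "|", fixed = TRUE)))
  expect_equal(igraph::vcount(g), length(items) + nrow(r))
  expect_equal(igraph::ecount(g), n_edges)
})
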