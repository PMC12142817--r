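test_that("normalization trims, collapses, case-folds and halves widths", {
  expect_equal(normalize_term("  Huang   Qi "), "huang qi")
  expect_equal(normalize_term("ＡＢＣ１２３"), "abc123")
  expect_equal(normalize_term("黄柏"), "黄柏")  # CJK compared as-is
  expect_equal(normalize_term("黄　柏"), "黄 柏") # ideographic space
})

test_that("make_lookup matches exactly after normalization and reports the rest", {
  ref <- lookup_table(c("黄蘗", "黄柏"), c("黄柏", "黄柏"))
  raw <- raw_records(data.frame(formula_id = "F1",
                                raw_term = c("黄柏", "黄蘗", "qqq-unknown")))
  lk <- make_lookup(raw, ref)
  expect_setequal(lk$raw, c("黄柏", "黄蘗"))
  expect_true(all(lk$standard == "黄柏"))
  expect_equal(unmatched_terms(lk), "qqq-unknown")
  # closure: raw terms exactly the reference keys -> nothing unmatched
  raw2 <- raw_records(data.frame(formula_id = "F1", raw_term = ref$raw))
  lk2 <- make_lookup(raw2, ref)
  expect_length(unmatched_terms(lk2), 0)
  expect_equal(nrow(lk2), 2)
  # partition invariant: matched + unmatched = distinct raw terms
  expect_equal(nrow(lk) + length(unmatched_terms(lk)), 3)
  expect_error(make_lookup(raw_records(data.frame(formula_id = character(),
                                                  raw_term = character())),
                           ref), "empty")
})

test_that("terms in the standard vocabulary are identity-mapped", {
  ref <- lookup_table("variant", "standardname")
  raw <- raw_records(data.frame(formula_id = "F1",
                                raw_term = c("variant", "standardname")))
  lk <- make_lookup(raw, ref)
  expect_equal(nrow(lk), 2)
  expect_true(all(lk$standard == "standardname"))
})

test_that("add_reference_terms extends, is idempotent, and refuses collisions", {
  empty <- lookup_table(character(), character())
  one <- add_reference_terms(empty, data.frame(raw = "myherb",
                                               standard = "MyHerb"))
  expect_equal(nrow(one), 1)
  again <- add_reference_terms(one, data.frame(raw = "myherb",
                                               standard = "MyHerb"))
  expect_equal(again$raw, one$raw)
  expect_equal(again$standard, one$standard)
  ref <- lookup_table("黄柏", "黄柏")
  expect_error(add_reference_terms(ref, data.frame(raw = "黄柏",
                                                   standard = "X")),
               "黄柏")
  expect_error(add_reference_terms(empty, data.frame(raw = " ",
                                                     standard = "X")),
               "non-empty")
})

test_that("clean_dataset standardizes, dedups within a formula, and logs drops", {
  lut <- lookup_table(c("a", "b", "zz"), c("A", "B", "ZZ"))
  raw <- data.frame(formula_id = c("F1", "F1", "F1", "F2", "F3"),
                    raw_term = c("a", "a", "b", "b", "nomatch"))
  expect_error(clean_dataset(raw, lut), "nomatch")
  ds <- clean_dataset(raw, lut, drop_unmatched = TRUE)
  expect_equal(ds$formulas$F1, c("A", "B"))
  expect_equal(ds$formulas$F2, "B")
  # F3 contained only unmatched terms -> dropped by default
  expect_equal(n_formulas(ds), 2)
  expect_equal(attr(ds, "n_unmatched_dropped"), 1L)
  expect_equal(attr(ds, "n_empty_dropped"), 1L)
  ds_keep <- clean_dataset(raw, lut, drop_unmatched = TRUE,
                           keep_empty = TRUE)
  expect_equal(n_formulas(ds_keep), 3)
  # empty input is a valid empty dataset
  empty <- clean_dataset(data.frame(formula_id = character(),
                                    raw_term = character()), lut)
  expect_equal(n_formulas(empty), 0)
})

test_that("clean_dataset is idempotent on already-clean data", {
  ds <- random_dataset(20, 10)
  long <- data.frame(formula_id = rep(names(ds$formulas),
                                      lengths(ds$formulas)),
                     raw_term = unlist(ds$formulas, use.names = FALSE))
  vocab <- unique(long$raw_term)
  lut <- lookup_table(vocab, vocab)
  ds2 <- clean_dataset(long, lut)
  expect_equal(ds2$formulas, ds$formulas)
})

test_that("wide encoding orders columns by frequency and round-trips exactly", {
  ds <- formula_dataset(list(F1 = c("A", "B"), F2 = "B"))
  m <- to_wide(ds)
  expect_equal(colnames(m), c("B", "A"))   # B freq 2 > A freq 1
  expect_equal(unname(m), rbind(c(1L, 1L), c(1L, 0L)))
  expect_equal(to_long(m)$formulas, ds$formulas)
  expect_equal(dim(to_wide(formula_dataset(list()))), c(0L, 0L))
  expect_error(to_long(matrix(c(0, 2), 1, 2,
                              dimnames = list("F1", c("a", "b")))),
               "non-binary")
})

test_that("wide/long round-trip is the identity on a random 50x30 incidence", {
  set.seed(11)
  ds <- random_dataset(50, 30, size_range = 3:12)
  ds2 <- to_long(to_wide(ds))
  expect_equal(ds2$formulas[names(ds$formulas)], ds$formulas)
})

test_that("freq_table matches a brute-force tally and its counts sum correctly", {
  ds <- formula_dataset(list(F1 = c("A", "B"), F2 = "B"))
  ft <- freq_table(ds)
  expect_equal(ft$term, c("B", "A"))
  expect_equal(ft$count, c(2L, 1L))
  expect_equal(ft$relative_frequency, c(1, 0.5))
  expect_equal(freq_table(formula_dataset(list(F1 = "A")))$count, 1L)
  set.seed(3)
  big <- random_dataset(200, 25, size_range = 2:8)
  ft2 <- freq_table(big)
  tally <- table(unlist(big$formulas))
  expect_equal(ft2$count[match(names(tally), ft2$term)],
               unname(as.integer(tally)))
  expect_equal(sum(ft2$count), sum(lengths(big$formulas)))
  expect_error(freq_table(big, "nosuchfield"), "unknown")
})
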