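# Tree induction, conditional probabilities and the event algebra.

ten_rows <- data.frame(
  A = c("0", "0", "0", "0", "1", "1", "1", "1", "1", "1"),
  B = c("0", "0", "1", "1", "0", "0", "0", "1", "1", "1"),
  target = c("0", "0", "0", "1", "0", "1", "1", "1", "0", "1"),
  stringsAsFactors = FALSE
)

test_that("thetas equal hand-counted relative frequencies on a 10-row fixture", {
  tr <- build_tree(ten_rows, c("A", "B"), "target")
  r <- realizations(tr)
  # root split: A=0 in 4/10 rows, A=1 in 6/10
  expect_equal(sum(r$prob[r$A == "0"]), 0.4, tolerance = 1e-12)
  expect_equal(sum(r$prob[r$A == "1"]), 0.6, tolerance = 1e-12)
  # branch points: P(B=1|A=0) = 2/4, P(B=1|A=1) = 3/6
  expect_equal(r$prob[r$A == "0" & r$B == "1"], 0.4 * (2 / 4), tolerance = 1e-12)
  expect_equal(r$prob[r$A == "1" & r$B == "1"], 0.6 * (3 / 6), tolerance = 1e-12)
  # leaf counts total the record count and class tallies match raw rows
  expect_equal(sum(r$n), nrow(ten_rows))
  expect_equal(r$n_1[r$A == "1" & r$B == "0"], 2)
})

test_that("a single record induces a single certain path", {
  tr <- build_tree(ten_rows[1, ], c("A", "B"), "target")
  r <- realizations(tr)
  expect_equal(nrow(r), 1L)
  expect_equal(r$prob, 1)
  expect_equal(r$n, 1)
})

test_that("induction rejects bad inputs", {
  expect_error(build_tree(ten_rows[0, ], c("A", "B"), "target"), "nonempty")
  expect_error(build_tree(ten_rows, c("A", "C"), "target"), "unknown feature")
  bad <- ten_rows
  bad$A[3] <- NA
  expect_error(build_tree(bad, c("A", "B"), "target"), "missing values")
  tri <- ten_rows
  tri$target[1] <- "2"
  expect_error(build_tree(tri, c("A", "B"), "target"), "binary")
  # constant feature is a legal degenerate chain
  const <- ten_rows
  const$A <- "0"
  expect_silent(tr <- build_tree(const, c("A", "B"), "target"))
  expect_equal(realizations(tr)$prob, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("realization probabilities are normalized and depths are uniform", {
  for (seed in 1:10) {
    fx <- random_fixture(seed, n_features = sample(2:5, 1), n_rows = 50)
    tr <- build_tree(fx$records, fx$feature_order, "target")
    r <- realizations(tr)
    expect_equal(sum(r$prob), 1, tolerance = 1e-9)
    expect_equal(sum(r$n), tr$record_count)
    expect_true(all(r$prob >= 0 & r$prob <= 1))
  }
})

test_that("conditional_probability matches brute-force row filtering", {
  tr <- build_tree(ten_rows, c("A", "B"), "target")
  # marginal prior with empty conditions
  expect_equal(conditional_probability(tr, list(), "1"),
               mean(ten_rows$target == "1"), tolerance = 1e-12)
  for (cond in list(list(A = "0"), list(B = "1"), list(A = "1", B = "0"))) {
    expect_equal(conditional_probability(tr, cond, "1"),
                 oracle_conditional(ten_rows, cond, "target", "1"),
                 tolerance = 1e-12)
  }
  # full-path conditions equal the leaf class fraction
  expect_equal(conditional_probability(tr, list(A = "1", B = "1"), "1"), 2 / 3,
               tolerance = 1e-12)
})

test_that("unsupported conditional queries are signalled", {
  d <- data.frame(A = c("0", "0", "1"), B = c("0", "0", "1"),
                  target = c("0", "1", "1"), stringsAsFactors = FALSE)
  tr <- build_tree(d, c("A", "B"), "target")
  expect_error(conditional_probability(tr, list(A = "1", B = "0"), "1"),
               class = "fptree_unsupported_query")
  expect_error(conditional_probability(tr, list(C = "0"), "1"), "unknown variable")
  expect_error(conditional_probability(tr, list(A = "0"), "malignant"), "unknown class")
})

test_that("event algebra obeys Boolean evaluation and complements", {
  tr <- build_tree(ten_rows, c("A", "B"), "target")
  a <- event_is("A", "0")
  b <- event_is("B", "1")
  # tautology and complement law
  expect_equal(event_probability(tr, a | !a), 1, tolerance = 1e-12)
  expect_equal(event_probability(tr, !(a & b)),
               1 - event_probability(tr, a & b), tolerance = 1e-9)
  expect_error(event_probability(tr, event_is("nope", "0")), "unknown variable")
})

test_that("event probabilities agree exactly with row-filter enumeration", {
  for (seed in 11:25) {
    fx <- random_fixture(seed, n_features = 3, n_rows = 40)
    tr <- build_tree(fx$records, fx$feature_order, "target")
    vals <- lapply(fx$feature_order, function(f) unique(fx$records[[f]]))
    e <- withr::with_seed(seed * 7, {
      pick <- function() event_is(s <- sample(fx$feature_order, 1),
                                  sample(vals[[match(s, fx$feature_order)]], 1))
      (pick() & !pick()) | pick()
    })
    expect_equal(event_probability(tr, e), oracle_event(fx$records, e),
                 tolerance = 1e-9)
  }
})

test_that("trees round-trip through JSON and export to DOT", {
  tr <- build_tree(ten_rows, c("A", "B"), "target")
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_equal(realizations(tr2), realizations(tr))
  expect_equal(tr2$feature_order, tr$feature_order)
  expect_equal(tr2$record_count, tr$record_count)
  expect_identical(tree_to_dot(tr2), tree_to_dot(tr))

  dot <- tree_to_dot(tr)
  expect_match(dot, "digraph", fixed = TRUE)
  expect_match(dot, "label=\"0.400\"", fixed = TRUE) # theta to 3 decimals
  expect_match(dot, "A IS 1", fixed = TRUE)
})
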