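# Membership-weighted traversal, fallback, thresholding.

test_that("fuzzy traversal equals exhaustive weighted path enumeration", {
  cfg <- toy_fuzzy_config()
  for (seed in 1:20) {
    rows <- toy_fuzzy_rows(seed, n = 70)
    model <- fpt_fit(rows, cfg)
    patients <- withr::with_seed(seed + 100, {
      data.frame(x = stats::runif(5, 0, 10),
                 g = sample(c("a", "b"), 5, replace = TRUE),
                 z = stats::runif(5, 0, 100))
    })
    for (i in seq_len(nrow(patients))) {
      stmts <- list(x = patients$x[i], g = patients$g[i], z = patients$z[i])
      got <- fuzzy_predict(model$tree, stmts, "1", fuzzy = cfg)
      want <- oracle_fuzzy_enum(model$tree, stmts, "1", fuzzy = cfg)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("degenerate fuzziness reduces to the crisp conditional", {
  cfg <- toy_fuzzy_config()
  rows <- toy_fuzzy_rows(3, n = 80)
  model <- fpt_fit(rows, cfg)
  # x = 9 and z = 90 have membership exactly 1 in the rising sets
  stmts <- list(x = 9, g = "a", z = 90)
  disc <- discretize_records(data.frame(x = 9, g = "a", z = 90), cfg)
  crisp_path <- list(x = disc$x, g = "a", z = disc$z)
  expect_equal(fuzzy_predict(model$tree, stmts, "1", fuzzy = cfg),
               conditional_probability(model$tree, crisp_path, "1"),
               tolerance = 1e-12)
})

test_that("missing and unseen statements fall back as specified", {
  d <- data.frame(A = c("0", "0", "1", "1"), B = c("x", "y", "x", "x"),
                  target = c("0", "1", "1", "1"), stringsAsFactors = FALSE)
  tr <- build_tree(d, c("A", "B"), "target")
  # variable absent: children averaged with weight 1/|children|
  expect_equal(fuzzy_predict(tr, list(B = "x"), "1"),
               mean(c(0, 1)), tolerance = 1e-12) # P(1|A=0,B=x)=0, P(1|A=1,B=x)=1
  # unseen value at a split: theta-weighted average over all children
  expect_equal(fuzzy_predict(tr, list(A = "1", B = "zz"), "1"),
               1, tolerance = 1e-12) # only child B=x below A=1
  expect_equal(fuzzy_predict(tr, list(A = "0", B = "zz"), "1"),
               0.5 * 0 + 0.5 * 1, tolerance = 1e-12)
  # empty statements: the marginal prior
  expect_equal(fuzzy_predict(tr, list(), "1"), 0.75, tolerance = 1e-12)
})

test_that("find_existing_conditions matches the brute-force subset search", {
  for (seed in 31:45) {
    fx <- random_fixture(seed, n_features = 4, n_rows = 25)
    tr <- build_tree(fx$records, fx$feature_order, "target")
    stmts <- withr::with_seed(seed, {
      as.list(stats::setNames(
        vapply(fx$feature_order, function(f) sample(c(unique(fx$records[[f]]), "Q"), 1),
               character(1)),
        fx$feature_order
      ))
    })
    got <- find_existing_conditions(tr, stmts)
    want <- oracle_largest_subset(fx$records, stmts, fx$feature_order)
    expect_identical(got, want)
  }
})

test_that("find_existing_conditions trivial cases", {
  fx <- random_fixture(1, n_features = 3, n_rows = 20)
  tr <- build_tree(fx$records, fx$feature_order, "target")
  # a training record is fully represented
  full <- as.list(fx$records[1, fx$feature_order])
  expect_identical(find_existing_conditions(tr, full), lapply(full, as.character))
  # empty input is a valid empty return
  expect_identical(find_existing_conditions(tr, list()), list())
  # unsupported pair drops the later statement
  d <- data.frame(A = c("1", "1", "0"), B = c("1", "1", "0"),
                  target = c("0", "1", "1"), stringsAsFactors = FALSE)
  tr2 <- build_tree(d, c("A", "B"), "target")
  expect_identical(find_existing_conditions(tr2, list(A = "1", B = "0")),
                   list(A = "1"))
})

test_that("threshold rule is inclusive at the cut-off", {
  # leaf fractions engineered to give prob_positive = 0.50 and 0.49
  mk <- function(n1, n0) {
    data.frame(A = "0", target = rep(c("1", "0"), c(n1, n0)), stringsAsFactors = FALSE)
  }
  cfg <- fpt_config("A", "target", "1", "0",
                    list(A = list(type = "binary", values = c("0", "1"))))
  m50 <- fpt_fit(mk(50, 50), cfg)
  p <- predict(m50, list(A = "0"))
  expect_equal(p$prob_positive, 0.5)
  expect_equal(p$label, "1") # >= 0.50 is positive
  m49 <- fpt_fit(mk(49, 51), cfg)
  expect_equal(predict(m49, list(A = "0"))$label, "0")
  # a raised threshold flips a 0.6 prediction to negative
  m60 <- fpt_fit(mk(60, 40), cfg)
  expect_equal(predict(m60, list(A = "0"), threshold = 0.8)$label, "0")
  expect_error(predict(m60, list(A = "0"), threshold = 1.2), "probability")
})

test_that("probabilities are complementary and bounded", {
  cfg <- toy_fuzzy_config()
  rows <- toy_fuzzy_rows(9, n = 60)
  model <- fpt_fit(rows, cfg)
  pats <- withr::with_seed(77, {
    data.frame(x = stats::runif(8, 0, 10), g = sample(c("a", "b"), 8, TRUE),
               z = stats::runif(8, 0, 100))
  })
  pred <- predict(model, pats)
  expect_equal(pred$prob_positive + pred$prob_negative, rep(1, 8), tolerance = 1e-9)
  expect_true(all(pred$prob_positive >= 0 & pred$prob_positive <= 1))
  expect_true(all(pred$support > 0))
})

test_that("crisp limit: step memberships make FPT and PT coincide", {
  # step membership functions located exactly at the crisp cuts
  step_cfg <- fpt_config(
    feature_order = c("x", "g", "z"), target = "target",
    positive_class = "1", negative_class = "0",
    variables = list(
      x = list(type = "fuzzy", universe = c(0, 10), crisp_threshold = 5,
               sets = list(fuzzy_set("HighX", rbind(c(5 - 1e-9, 0), c(5, 1))))),
      g = list(type = "binary", values = c("a", "b")),
      z = list(type = "fuzzy", universe = c(0, 100), crisp_threshold = 50,
               sets = list(fuzzy_set("HighZ", rbind(c(50 - 1e-9, 0), c(50, 1)))))
    ))
  for (seed in 51:56) {
    rows <- toy_fuzzy_rows(seed, n = 60)
    model <- fpt_fit(rows, step_cfg)
    pats <- withr::with_seed(seed, {
      data.frame(x = stats::runif(6, 0, 10), g = sample(c("a", "b"), 6, TRUE),
                 z = stats::runif(6, 0, 100))
    })
    fz <- predict(model, pats)
    cr <- crisp_predict(model, pats)
    expect_equal(fz$prob_positive, cr$prob_positive, tolerance = 1e-9)
    expect_identical(fz$label, cr$label)
  }
})

test_that("crisp prediction matches filter-and-count on discretized rows", {
  cfg <- toy_fuzzy_config()
  rows <- toy_fuzzy_rows(13, n = 50)
  model <- fpt_fit(rows, cfg)
  disc <- discretize_records(rows, cfg)
  pat <- data.frame(x = 7.7, g = "b", z = 12)
  dp <- discretize_records(pat, cfg)
  want <- oracle_conditional(disc, as.list(dp[1, c("x", "g", "z")]), "target", "1")
  if (!is.na(want)) {
    expect_equal(crisp_predict(model, pat)$prob_positive, want, tolerance = 1e-12)
  }
})

test_that("prediction is monotone in membership weight", {
  # two-leaf tree: HighX leaf has positive fraction 1, NotHighX leaf 0
  d <- data.frame(x = c(1, 1, 9, 9), target = c("0", "0", "1", "1"),
                  stringsAsFactors = FALSE)
  cfg <- fpt_config("x", "target", "1", "0",
                    list(x = list(type = "fuzzy", universe = c(0, 10),
                                  crisp_threshold = 5,
                                  sets = list(fuzzy_set("HighX", rbind(c(2, 0), c(8, 1)))))))
  model <- fpt_fit(d, cfg)
  vals <- seq(2, 8, by = 0.5)
  probs <- vapply(vals, function(v) predict(model, list(x = v))$prob_positive, numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_equal(probs[1], 0, tolerance = 1e-12)
  expect_equal(probs[length(probs)], 1, tolerance = 1e-12)
})

test_that("a patient with no represented conditions gets the prior with a warning", {
  d <- data.frame(A = c("0", "0", "1"), target = c("0", "1", "1"),
                  stringsAsFactors = FALSE)
  cfg <- fpt_config("A", "target", "1", "0",
                    list(A = list(type = "binary", values = c("0", "1", "2"))))
  model <- fpt_fit(d, cfg)
  expect_warning(p <- predict(model, list(A = "2")), "class prior")
  expect_equal(p$prob_positive, 2 / 3, tolerance = 1e-12)
  expect_equal(p$dropped, "A")
})
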