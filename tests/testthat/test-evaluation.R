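# Stratified splitting, confusion metrics, bootstrap harness.

test_that("stratified split allocates classes proportionally and deterministically", {
  d <- data.frame(x = seq_len(100),
                  target = rep(c("1", "0"), c(30, 70)),
                  stringsAsFactors = FALSE)
  parts <- stratified_split(d, "target", 0.2, seed = 11)
  expect_equal(sum(parts$test$target == "1"), 6)
  expect_equal(nrow(parts$test), 20)
  expect_equal(sum(parts$train$target == "1"), 24)
  # per-class proportions within one record of the full data
  for (cl in c("0", "1")) {
    full <- mean(d$target == cl)
    expect_lt(abs(sum(parts$test$target == cl) - full * 20), 1 + 1e-9)
    expect_lt(abs(sum(parts$train$target == cl) - full * 80), 1 + 1e-9)
  }
  # determinism and disjointness
  parts2 <- stratified_split(d, "target", 0.2, seed = 11)
  expect_identical(parts, parts2)
  expect_equal(sort(c(parts$train$x, parts$test$x)), d$x)
  # too-small classes error
  tiny <- data.frame(target = c("1", rep("0", 9)))
  expect_error(stratified_split(tiny, "target", 0.2, seed = 1), "too few records")
  expect_error(stratified_split(d, "target", 1.2, seed = 1), "between 0 and 1")
})

test_that("confusion metrics follow the standard closed forms", {
  m <- confusion_metrics(tp = 8, fp = 2, fn = 1, tn = 89)
  expect_equal(unname(m["accuracy"]), 0.97, tolerance = 1e-12)
  expect_equal(unname(m["sensitivity"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 89 / 91, tolerance = 1e-12)
  expect_equal(unname(m["precision"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(confusion_metrics(5, 0, 0, 5)), rep(1, 4))
  # zero denominators are flagged undefined, not errors
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)["precision"]))
  expect_error(confusion_metrics(-1, 0, 0, 0), "nonnegative")
})

test_that("confusion metrics agree with re-derivation from label vectors", {
  for (seed in 1:10) {
    lab <- withr::with_seed(seed, {
      list(truth = stats::rbinom(40, 1, 0.4) == 1,
           pred = stats::rbinom(40, 1, 0.5) == 1)
    })
    m <- confusion_metrics(tp = sum(lab$pred & lab$truth),
                           fp = sum(lab$pred & !lab$truth),
                           fn = sum(!lab$pred & lab$truth),
                           tn = sum(!lab$pred & !lab$truth))
    expect_equal(unname(m["accuracy"]), mean(lab$pred == lab$truth), tolerance = 1e-12)
    if (any(lab$truth)) {
      expect_equal(unname(m["sensitivity"]), mean(lab$pred[lab$truth]), tolerance = 1e-12)
    }
  }
})

# An oracle trainer that reads off the true class: all metrics must be 100%
# with zero-width CIs.
oracle_trainer <- function(train) function(newdata) as.numeric(newdata$target == "1")

test_that("the bootstrap harness returns perfect zero-width CIs for an oracle model", {
  d <- data.frame(x = sample(c("a", "b"), 200, TRUE),
                  target = rep(c("1", "0"), c(60, 140)), stringsAsFactors = FALSE)
  rep1 <- bootstrap_evaluate(oracle_trainer, d, target = "target", positive_class = "1",
                             n_bootstraps = 25, threshold = 0.5, seed = 5)
  expect_equal(rep1$estimate, rep(100, 4), tolerance = 1e-12)
  expect_equal(rep1$ci_lower, rep(100, 4), tolerance = 1e-12)
  expect_equal(rep1$ci_upper, rep(100, 4), tolerance = 1e-12)
  # seed reproducibility of the full report
  rep2 <- bootstrap_evaluate(oracle_trainer, d, target = "target", positive_class = "1",
                             n_bootstraps = 25, threshold = 0.5, seed = 5)
  expect_identical(rep1, rep2)
})

test_that("bootstrap evaluation of an FPT model is reproducible and bounded", {
  spec <- thyroid_cohort_spec(n = 240, prevalence = 0.3)
  cohort <- generate_cohort(spec, seed = 42)
  r1 <- bootstrap_evaluate(spec$config, cohort, n_bootstraps = 12, seed = 7,
                           test_fraction = 0.25)
  r2 <- bootstrap_evaluate(spec$config, cohort, n_bootstraps = 12, seed = 7,
                           test_fraction = 0.25)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_lower <= r1$estimate + 1e-9))
  expect_true(all(r1$estimate <= r1$ci_upper + 1e-9))
  expect_true(all(r1$estimate >= 0 & r1$estimate <= 100, na.rm = TRUE))
})

test_that("percentile CI width converges to the metric's true sampling spread", {
  # a coin-flip model: accuracy per replicate ~ Binomial(n_test, 0.5) / n_test,
  # whose 95% spread is analytically ~ 2 * 1.96 * 50 * sqrt(0.25/100) = 19.6 points
  coin_trainer <- function(train) function(newdata) stats::runif(nrow(newdata))
  d <- data.frame(target = rep(c("1", "0"), 100), stringsAsFactors = FALSE)
  width <- function(n_b) {
    r <- bootstrap_evaluate(coin_trainer, d, target = "target", positive_class = "1",
                            n_bootstraps = n_b, threshold = 0.5, seed = 3,
                            test_fraction = 0.5)
    r$ci_upper[r$metric == "accuracy"] - r$ci_lower[r$metric == "accuracy"]
  }
  withr::with_seed(19, {
    expect_lt(abs(width(500) - 19.6), 5)
  })
})

test_that("raising the threshold never raises sensitivity nor lowers specificity", {
  set <- withr::with_seed(8, {
    list(probs = stats::runif(300), truth = stats::rbinom(300, 1, 0.35) == 1)
  })
  ms <- lapply(seq(0.1, 0.9, by = 0.1), function(t) {
    pred <- set$probs >= t
    confusion_metrics(sum(pred & set$truth), sum(pred & !set$truth),
                      sum(!pred & set$truth), sum(!pred & !set$truth))
  })
  sens <- vapply(ms, `[[`, numeric(1), "sensitivity")
  spec <- vapply(ms, `[[`, numeric(1), "specificity")
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("replicates that lose a class are skipped and logged", {
  d <- data.frame(target = rep(c("1", "0"), c(2, 38)), stringsAsFactors = FALSE)
  r <- bootstrap_evaluate(oracle_trainer, d, target = "target", positive_class = "1",
                          n_bootstraps = 30, threshold = 0.5, seed = 2,
                          test_fraction = 0.5)
  expect_gte(attr(r, "n_skipped"), 1)
})
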