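#' Stratified train/test split
#'
#' Partitions records so that class proportions in both partitions match the
#' full data to within one record per class (proportional allocation with
#' rounding), as required for a representative held-out set.
#'
#' @param records Data.frame of records.
#' @param target Name of the class column.
#' @param test_fraction Fraction of each class allocated to the test set
#'   (strictly between 0 and 1).
#' @param seed Integer seed; the same seed yields the identical split.
#' @return A list with data.frames `train` and `test`.
#' @export
stratified_split <- function(records, target, test_fraction, seed) {
  stopifnot(is.data.frame(records))
  if (!is_number(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    fpt_stop("'test_fraction' must lie strictly between 0 and 1")
  }
  y <- as.character(records[[target]])
  classes <- sort(unique(y))
  if (length(classes) < 2L) fpt_stop("both classes must be present for a stratified split")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(y == cl)
      n_test <- round(length(idx) * test_fraction)
      if (n_test < 1L || n_test >= length(idx)) {
        fpt_stop("class '%s' has too few records (%d) for test_fraction %.2f",
                 cl, length(idx), test_fraction)
      }
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  list(train = records[-test_idx, , drop = FALSE],
       test = records[test_idx, , drop = FALSE])
}

#' Classification metrics from a confusion table
#'
#' Standard definitions: accuracy `(tp+tn)/N`, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`. A ratio with a zero
#' denominator is flagged undefined (`NA`) so callers can exclude it from
#' aggregation.
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return Named numeric vector (`accuracy`, `sensitivity`, `specificity`,
#'   `precision`) on the 0–1 scale, `NA` where undefined.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || anyNA(counts)) fpt_stop("confusion counts must be nonnegative")
  n <- sum(counts)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = ratio(tp + tn, n),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp))
}

#' A trainer callable for the bootstrap harness
#'
#' The evaluation harness accepts any "trainer": a function that takes a
#' training data.frame and returns a prediction function mapping a test
#' data.frame to positive-class probabilities. This adapter builds trainers
#' for the package's own models; baselines (logistic regression, decision
#' trees, ...) plug in through the same contract.
#'
#' @param config An `fpt_config`.
#' @param mode `"fuzzy"` (FPT) or `"crisp"` (traditional PT).
#' @return A trainer function.
#' @export
fpt_trainer <- function(config, mode = c("fuzzy", "crisp")) {
  mode <- match.arg(mode)
  force(config)
  function(train) {
    model <- fpt_fit(train, config)
    function(newdata) {
      pred <- if (mode == "fuzzy") {
        predict(model, newdata)
      } else {
        crisp_predict(model, newdata)
      }
      pred$prob_positive
    }
  }
}

#' Bootstrap evaluation of a classifier
#'
#' Reproduces the evaluation protocol of the case studies: the data set is
#' split once into stratified train and test partitions; per replicate the
#' training partition is resampled with replacement, the model is refit, the
#' fixed test partition is predicted at the given threshold, and the four
#' metrics are computed. Point estimates are means across replicates and the
#' 95% confidence intervals are 2.5/97.5 percentiles. Replicates missing a
#' class are skipped (logged); undefined ratios are excluded per metric.
#'
#' All randomness flows from `seed` via one substream per replicate
#' (`seed + b`), so reports are reproducible.
#'
#' @param trainer A trainer function (see [fpt_trainer()]) or an
#'   `fpt_config`, in which case the package's fuzzy model is trained.
#' @param records Full data set (data.frame).
#' @param target Class column name; defaults to the config's when `trainer`
#'   is an `fpt_config`.
#' @param positive_class Positive class label; same default.
#' @param n_bootstraps Number of replicates (>= 2; the case studies used 1000
#'   and 250).
#' @param threshold Classification cut-off.
#' @param seed Integer master seed.
#' @param test_fraction Held-out fraction for the initial stratified split.
#' @return An object of class `fpt_metric_report`: a data.frame with one row
#'   per metric (`estimate`, `ci_lower`, `ci_upper`, in percent) and
#'   attributes `n_bootstraps`, `threshold`, `seed`, `n_skipped`,
#'   `n_undefined`.
#' @export
bootstrap_evaluate <- function(trainer, records, target = NULL, positive_class = NULL,
                               n_bootstraps = 1000, threshold = 0.5, seed = 1,
                               test_fraction = 0.2) {
  if (inherits(trainer, "fpt_config")) {
    target <- target %||% trainer$target
    positive_class <- positive_class %||% trainer$positive_class
    trainer <- fpt_trainer(trainer)
  }
  if (!is.function(trainer)) fpt_stop("'trainer' must be a function or an fpt_config")
  if (is.null(target) || is.null(positive_class)) {
    fpt_stop("'target' and 'positive_class' are required for a plain trainer")
  }
  if (!is_number(n_bootstraps) || n_bootstraps < 2) fpt_stop("'n_bootstraps' must be >= 2")
  if (seed + n_bootstraps >= 2^31) fpt_stop("'seed' too large")

  parts <- stratified_split(records, target, test_fraction, seed)
  truth <- as.character(parts$test[[target]]) == as.character(positive_class)
  fpt_log("stratified split: %d train / %d test (%d positives in test)",
          nrow(parts$train), nrow(parts$test), sum(truth))

  metric_names <- c("accuracy", "sensitivity", "specificity", "precision")
  reps <- matrix(NA_real_, nrow = n_bootstraps, ncol = 4,
                 dimnames = list(NULL, metric_names))
  skipped <- 0L
  for (b in seq_len(n_bootstraps)) {
    boot <- with_seed(seed + b, {
      parts$train[sample(nrow(parts$train), replace = TRUE), , drop = FALSE]
    })
    if (length(unique(as.character(boot[[target]]))) < 2L) {
      skipped <- skipped + 1L
      fpt_log("replicate %d skipped: resample lost a class", b)
      next
    }
    probs <- trainer(boot)(parts$test)
    pred <- probs >= threshold
    reps[b, ] <- confusion_metrics(tp = sum(pred & truth), fp = sum(pred & !truth),
                                   fn = sum(!pred & truth), tn = sum(!pred & !truth))
  }
  done <- rowSums(!is.na(reps)) > 0
  n_undefined <- colSums(is.na(reps[done, , drop = FALSE]))
  if (any(n_undefined > 0)) {
    fpt_log("undefined metric values excluded from CIs: %s",
            paste(metric_names, n_undefined, sep = "=", collapse = ", "))
  }
  summary_row <- function(x) {
    x <- x[!is.na(x)] * 100
    c(estimate = mean(x), stats::quantile(x, c(0.025, 0.975), names = FALSE))
  }
  out <- as.data.frame(t(apply(reps, 2, summary_row)))
  names(out) <- c("estimate", "ci_lower", "ci_upper")
  out <- cbind(metric = metric_names, out)
  rownames(out) <- NULL
  structure(out, class = c("fpt_metric_report", class(out)),
            n_bootstraps = n_bootstraps, threshold = threshold, seed = seed,
            n_skipped = skipped, n_undefined = n_undefined)
}

#' @export
print.fpt_metric_report <- function(x, ...) {
  cat(sprintf("Bootstrap evaluation: %d replicates, threshold %.2f, seed %d\n",
              attr(x, "n_bootstraps"), attr(x, "threshold"), attr(x, "seed")))
  if (attr(x, "n_skipped") > 0) {
    cat(sprintf("  (%d replicates skipped: missing class)\n", attr(x, "n_skipped")))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %5.1f%% [%.1f-%.1f]\n", x$metric[i], x$estimate[i],
                x$ci_lower[i], x$ci_upper[i]))
  }
  invisible(x)
}
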