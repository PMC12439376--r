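#' Patient records
#'
#' A patient is described by at most one statement per variable: crisp
#' variables carry a category/term label, fuzzy variables carry the raw
#' numeric measurement (in universe units) that traversal will fuzzify.
#'
#' @param statements Named list/vector of crisp statements (variable = value).
#' @param raw_values Named numeric vector of raw measurements for fuzzy
#'   variables.
#' @param outcome Optional known class label.
#' @return An object of class `fpt_patient`.
#' @examples
#' patient_record(
#'   statements = list(class = "TIR3B", gender = "Female"),
#'   raw_values = c(age = 48, nodule_mm = 18)
#' )
#' @export
patient_record <- function(statements = list(), raw_values = numeric(0), outcome = NULL) {
  stmts <- as_statement_list(statements)
  if (length(raw_values)) {
    if (is.null(names(raw_values)) || any(names(raw_values) == "")) {
      fpt_stop("'raw_values' must be named by variable")
    }
    if (!is.numeric(raw_values) || any(!is.finite(raw_values))) {
      fpt_stop("'raw_values' must be finite numbers")
    }
    overlap <- intersect(names(stmts), names(raw_values))
    if (length(overlap)) {
      fpt_stop("variable(s) %s appear both as statements and raw values",
               paste(overlap, collapse = ", "))
    }
    stmts <- c(stmts, as.list(raw_values))
  }
  structure(list(statements = stmts,
                 outcome = if (!is.null(outcome)) as.character(outcome)),
            class = "fpt_patient")
}

#' @export
print.fpt_patient <- function(x, ...) {
  cat("Patient record:\n")
  for (v in names(x$statements)) {
    cat(sprintf("  %s IS %s\n", v, format(x$statements[[v]])))
  }
  if (!is.null(x$outcome)) cat(sprintf("  known outcome: %s\n", x$outcome))
  invisible(x)
}

# Coerce the accepted patient spellings into the internal statement list,
# restricted to tree variables. Numeric entries for fuzzy variables stay
# numeric; numeric entries for crisp variables become labels.
patient_statements <- function(patient, config) {
  stmts <- if (inherits(patient, "fpt_patient")) patient$statements else as_statement_list(patient)
  unknown <- setdiff(names(stmts), config$feature_order)
  if (length(unknown)) {
    fpt_stop("patient references variable(s) outside the model: %s",
             paste(unknown, collapse = ", "))
  }
  fz <- fuzzy_variables(config)
  lapply(stats::setNames(names(stmts), names(stmts)), function(v) {
    val <- stmts[[v]]
    if (is.numeric(val) && !v %in% fz) as.character(val) else val
  })
}

#' Fuzzy prediction by membership-weighted tree traversal
#'
#' Recursively computes the probability that a patient described by
#' `statements` belongs to class `cls`. The recursion follows five cases:
#' (i) at a leaf, return the class fraction of the leaf counts; (ii) with no
#' statements left, return the conditional class probability of the path so
#' far (the subtree class fraction); (iii) when the next statement names the
#' variable the children split on, weight each matching branch by its
#' (renormalized) membership degree — degree 1 on the single matching child
#' for a crisp variable, graded weights over all branches for a fuzzy one —
#' and sum the weighted recursive results; (iv) when the variable splits here
#' but the stated value has no matching child, return the theta-weighted
#' average over all children; (v) when the patient carries no statement for
#' the splitting variable, average the children with weight `1/|children|`.
#'
#' @param tree An `fpt_tree`.
#' @param statements Named list: character values for crisp variables, raw
#'   numeric values for fuzzy ones (see [patient_record()]).
#' @param cls Class label whose probability is requested.
#' @param fuzzy Named list of [linguistic_variable()] objects (or an
#'   `fpt_config`), used to fuzzify raw numeric statement values. May be
#'   empty for a fully crisp query.
#' @param node Node to start from (default: the tree root). Supplying a node
#'   id is also accepted.
#' @return A probability.
#' @export
fuzzy_predict <- function(tree, statements, cls, fuzzy = NULL, node = NULL) {
  stopifnot(inherits(tree, "fpt_tree"))
  cls <- as.character(cls)
  if (!cls %in% tree$class_levels) fpt_stop("unknown class label '%s'", cls)
  if (inherits(fuzzy, "fpt_config")) {
    cfg <- fuzzy
    fuzzy <- lapply(cfg$variables[fuzzy_variables(cfg)], `[[`, "linguistic")
  }
  if (is.null(node)) {
    node <- tree$root
  } else if (is.numeric(node)) {
    node <- find_node(tree, node)
  } else if (!is.list(node) || is.null(node$id)) {
    fpt_stop("'node' must be a tree node or node id")
  } else {
    node <- find_node(tree, node$id) # errors if the node is not in this tree
  }
  stmts <- as_statement_list(statements)
  unknown <- setdiff(names(stmts), tree$feature_order)
  if (length(unknown)) {
    fpt_stop("statement variable(s) not in the tree: %s", paste(unknown, collapse = ", "))
  }
  # statements for variables already fixed on the path to `node` are spent
  stmts <- stmts[setdiff(names(stmts), names(node$statements))]
  fuzzy_predict_rec(tree, node, stmts, cls, fuzzy)
}

fuzzy_predict_rec <- function(tree, node, stmts, cls, fuzzy) {
  if (is_leaf(node)) {                                   # (i)
    return(node$class_counts[[cls]] / sum(node$class_counts))
  }
  if (length(stmts) == 0L) {                             # (ii)
    return(node$counts[[cls]] / sum(node$counts))
  }
  f <- node_split_variable(tree, node)
  kids <- node$transitions
  if (!f %in% names(stmts)) {                            # (v) variable absent
    vals <- vapply(kids, function(tr) fuzzy_predict_rec(tree, tr$child, stmts, cls, fuzzy),
                   numeric(1))
    return(mean(vals))
  }
  val <- stmts[[f]]
  rest <- stmts[setdiff(names(stmts), f)]
  child_vals <- vapply(kids, function(tr) {
    s <- tr$child$statements
    s[[length(s)]]
  }, character(1))

  if (is.numeric(val)) {
    lv <- fuzzy[[f]]
    if (is.null(lv)) {
      fpt_stop("variable '%s' has a raw numeric value but no linguistic variable", f)
    }
    w <- branch_weights(lv, val)
    present <- w[child_vals]
    present[is.na(present)] <- 0
    if (sum(present) > 0) {                              # (iii) fuzzy: all branches
      present <- present / sum(present)
      vals <- vapply(kids, function(tr) fuzzy_predict_rec(tree, tr$child, rest, cls, fuzzy),
                     numeric(1))
      return(sum(present * vals))
    }
    # every positively-weighted term is unsupported here: treat as unseen value (iv)
  } else if (val %in% child_vals) {                      # (iii) crisp: degree 1
    child <- kids[[match(val, child_vals)]]$child
    return(fuzzy_predict_rec(tree, child, rest, cls, fuzzy))
  }
  thetas <- vapply(kids, `[[`, numeric(1), "theta")      # (iv) unseen value
  vals <- vapply(kids, function(tr) fuzzy_predict_rec(tree, tr$child, rest, cls, fuzzy),
                 numeric(1))
  sum(thetas * vals)
}

# ---- support and fallback ----------------------------------------------

# Matrix [realization x statement] of matches, plus leaf record counts.
# A crisp statement matches by equality; a raw numeric statement for a fuzzy
# variable matches every term carrying positive membership weight.
# `reals` lets callers reuse one realization table across many patients.
support_matrix <- function(tree, stmts, fuzzy, reals = NULL) {
  if (is.null(reals)) reals <- realizations(tree)
  m <- matrix(TRUE, nrow = nrow(reals), ncol = length(stmts),
              dimnames = list(NULL, names(stmts)))
  for (v in names(stmts)) {
    val <- stmts[[v]]
    if (is.numeric(val) && !is.null(fuzzy[[v]])) {
      w <- branch_weights(fuzzy[[v]], val)
      hit <- w[reals[[v]]] > 0
      hit[is.na(hit)] <- FALSE
      m[, v] <- hit
    } else if (is.numeric(val)) {
      m[, v] <- TRUE
    } else {
      m[, v] <- reals[[v]] == as.character(val)
    }
  }
  list(match = m, n = reals$n)
}

#' Largest represented condition set
#'
#' Called when a patient is not fully represented in the training data (no
#' tree path supports every statement). Returns the largest subset of the
#' input statements for which a supporting path exists, so prediction can use
#' the weighted average of similar training cases. Among equally large
#' subsets, the one retaining the earliest features in `feature_order` is
#' chosen.
#'
#' @param tree An `fpt_tree`.
#' @param statements Named statement list (crisp labels and/or raw numeric
#'   values for fuzzy variables).
#' @param fuzzy Named list of linguistic variables or an `fpt_config` (needed
#'   only when raw numeric statements are present).
#' @param reals Optional precomputed [realizations()] table of `tree`, so
#'   batch callers can reuse one enumeration across many patients.
#' @return The retained subset of `statements` (possibly empty).
#' @export
find_existing_conditions <- function(tree, statements, fuzzy = NULL, reals = NULL) {
  stopifnot(inherits(tree, "fpt_tree"))
  if (inherits(fuzzy, "fpt_config")) {
    cfg <- fuzzy
    fuzzy <- lapply(cfg$variables[fuzzy_variables(cfg)], `[[`, "linguistic")
  }
  stmts <- as_statement_list(statements)
  if (length(stmts) == 0L) return(stmts)
  unknown <- setdiff(names(stmts), tree$feature_order)
  if (length(unknown)) {
    fpt_stop("statement variable(s) not in the tree: %s", paste(unknown, collapse = ", "))
  }
  # order statements by feature_order so the tie-break is well defined
  stmts <- stmts[intersect(tree$feature_order, names(stmts))]
  sm <- support_matrix(tree, stmts, fuzzy, reals = reals)
  k <- length(stmts)
  best <- logical(k)
  best_size <- -1L
  # exhaustive over subsets (k <= ~10): maximize size; ties prefer subsets
  # keeping earlier features.
  masks <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  for (i in seq_len(nrow(masks))) {
    keep <- as.logical(masks[i, ])
    size <- sum(keep)
    if (size < best_size) next
    supported <- any(rowSums(sm$match[, keep, drop = FALSE]) == size)
    if (!supported) next
    if (size > best_size || earlier_preferred(keep, best)) {
      best <- keep
      best_size <- size
    }
  }
  stmts[best]
}

# keep1 beats keep2 when the first feature where they differ is kept by keep1
earlier_preferred <- function(keep1, keep2) {
  d <- which(keep1 != keep2)
  length(d) > 0L && keep1[d[1]]
}

# Is the full statement set represented by at least one path?
is_represented <- function(tree, stmts, fuzzy, reals = NULL) {
  if (length(stmts) == 0L) return(TRUE)
  sm <- support_matrix(tree, stmts, fuzzy, reals = reals)
  any(rowSums(sm$match) == length(stmts))
}

# Training records compatible with the statements (support of the query).
support_count <- function(tree, stmts, fuzzy, reals = NULL) {
  if (length(stmts) == 0L) return(tree$record_count)
  sm <- support_matrix(tree, stmts, fuzzy, reals = reals)
  sum(sm$n[rowSums(sm$match) == length(stmts)])
}

# ---- user-facing prediction --------------------------------------------

predict_one <- function(model, stmts, threshold, mode = c("fuzzy", "crisp"),
                        reals = NULL) {
  mode <- match.arg(mode)
  tree <- model$tree
  config <- model$config
  if (is.null(reals)) reals <- realizations(tree)
  lingvars <- lapply(config$variables[fuzzy_variables(config)], `[[`, "linguistic")

  if (mode == "crisp") {
    # force memberships to {0,1}: discretize raw values by the crisp cuts
    for (v in names(stmts)) {
      if (is.numeric(stmts[[v]])) {
        cfgv <- config$variables[[v]]
        if (is.null(cfgv) || cfgv$type != "fuzzy") {
          fpt_stop("variable '%s' is numeric but not fuzzy", v)
        }
        stmts[[v]] <- crisp_assign(cfgv$linguistic, stmts[[v]], cfgv$crisp_threshold)
      }
    }
    lingvars <- list()
  }

  dropped <- character(0)
  if (!is_represented(tree, stmts, lingvars, reals = reals)) {
    kept <- find_existing_conditions(tree, stmts, lingvars, reals = reals)
    dropped <- setdiff(names(stmts), names(kept))
    fpt_log("patient not fully represented; dropping {%s}, predicting from %d condition(s)",
            paste(dropped, collapse = ", "), length(kept))
    stmts <- kept
  }
  if (length(stmts) == 0L) {
    warning("no patient condition is represented in the tree; returning the class prior",
            call. = FALSE)
  }
  p_pos <- fuzzy_predict(tree, stmts, config$positive_class, fuzzy = lingvars)
  p_neg <- fuzzy_predict(tree, stmts, config$negative_class, fuzzy = lingvars)
  label <- if (p_pos >= threshold) config$positive_class else config$negative_class
  data.frame(prob_negative = p_neg, prob_positive = p_pos, label = label,
             threshold = threshold,
             support = support_count(tree, stmts, lingvars, reals = reals),
             dropped = paste(dropped, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Predict with a fuzzy probability tree model
#'
#' Fuzzifies the patient's raw values into branch membership weights and runs
#' the membership-weighted traversal ([fuzzy_predict()]); patients not fully
#' represented in the training data fall back to their largest represented
#' condition set ([find_existing_conditions()]), with the dropped variables
#' handled by uniform child weighting. The predicted label is the positive
#' class iff its probability is greater than or equal to the threshold
#' (boundary inclusive).
#'
#' @param object An `fpt_model` from [fpt_fit()].
#' @param patients A [patient_record()], a named list of statements, or a
#'   data.frame with one row per patient (fuzzy variables numeric).
#' @param threshold Classification cut-off; defaults to the configured one
#'   (0.50 unless changed). Raise it when only the most certain positive
#'   calls should be made.
#' @param ... Unused.
#' @return A data.frame of class `fpt_prediction` with one row per patient:
#'   `prob_negative`, `prob_positive`, `label`, `threshold`, `support` (number
#'   of training records compatible with the conditions used), and `dropped`
#'   (comma-separated variables removed by the fallback, if any).
#' @export
predict.fpt_model <- function(object, patients, threshold = NULL, ...) {
  threshold <- threshold %||% object$config$threshold
  if (!is_number(threshold) || threshold < 0 || threshold > 1) {
    fpt_stop("'threshold' must be a probability")
  }
  rows <- patients_as_rows(object$config, patients)
  reals <- realizations(object$tree)
  out <- do.call(rbind, lapply(rows, predict_one, model = object,
                               threshold = threshold, mode = "fuzzy",
                               reals = reals))
  class(out) <- c("fpt_prediction", class(out))
  out
}

#' Crisp (traditional probability tree) prediction
#'
#' Follows the single path selected by the crisp thresholds of the fuzzy
#' variables — the traditional probability-tree prediction, equal to
#' [fuzzy_predict()] with every membership forced to 0 or 1. Unseen paths
#' fall back through [find_existing_conditions()].
#'
#' @inheritParams predict.fpt_model
#' @param model An `fpt_model`.
#' @return A data.frame of class `fpt_prediction` (see [predict.fpt_model()]).
#' @export
crisp_predict <- function(model, patients, threshold = NULL) {
  stopifnot(inherits(model, "fpt_model"))
  threshold <- threshold %||% model$config$threshold
  rows <- patients_as_rows(model$config, patients)
  reals <- realizations(model$tree)
  out <- do.call(rbind, lapply(rows, predict_one, model = model,
                               threshold = threshold, mode = "crisp",
                               reals = reals))
  class(out) <- c("fpt_prediction", class(out))
  out
}

# Accept one patient (record/list) or a data.frame of many.
patients_as_rows <- function(config, patients) {
  if (is.data.frame(patients)) {
    keep <- intersect(names(patients), config$feature_order)
    lapply(seq_len(nrow(patients)), function(i) {
      patient_statements(as.list(patients[i, keep, drop = FALSE]), config)
    })
  } else {
    list(patient_statements(patients, config))
  }
}

#' @export
print.fpt_prediction <- function(x, ...) {
  cat(sprintf("FPT prediction (threshold %.2f):\n", x$threshold[1]))
  print.data.frame(x[, c("prob_negative", "prob_positive", "label", "support")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}
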