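#' Model configuration
#'
#' A model configuration declares the expert-chosen feature order, the binary
#' target and its positive label, the type of each feature (categorical,
#' binary, or fuzzy-numeric), the fuzzy definitions (universe, sets, knots,
#' units), the crisp thresholds used in traditional probability-tree mode,
#' and the default classification threshold.
#'
#' @param feature_order Character vector of feature names, root to leaf.
#' @param target Name of the binary class column.
#' @param positive_class Label of the positive (disease) class.
#' @param negative_class Label of the negative class.
#' @param variables Named list, one entry per feature. Each entry is a list
#'   with `type` in `c("categorical", "binary", "fuzzy")`; fuzzy entries also
#'   carry `universe`, `sets` (a list of [fuzzy_set()] objects, or one set
#'   whose complement is auto-generated), `crisp_threshold` and optional
#'   `units`.
#' @param threshold Default classification cut-off (positive iff the positive
#'   class probability is `>= threshold`).
#' @return An object of class `fpt_config`.
#' @export
fpt_config <- function(feature_order, target, positive_class, negative_class,
                       variables, threshold = 0.5) {
  feature_order <- as.character(feature_order)
  if (!length(feature_order)) fpt_stop("feature_order must be nonempty")
  if (!is_string(target)) fpt_stop("missing or invalid 'target'")
  if (!is_number(threshold) || threshold < 0 || threshold > 1) {
    fpt_stop("'threshold' must be a probability")
  }
  if (!is.list(variables) || is.null(names(variables))) {
    fpt_stop("'variables' must be a named list, one entry per feature")
  }
  untyped <- setdiff(feature_order, names(variables))
  if (length(untyped)) {
    fpt_stop("feature(s) missing from 'variables': %s", paste(untyped, collapse = ", "))
  }
  vars <- list()
  for (f in feature_order) {
    v <- variables[[f]]
    type <- v$type %||% fpt_stop("variable '%s': missing 'type'", f)
    if (!type %in% c("categorical", "binary", "fuzzy")) {
      fpt_stop("variable '%s': unknown type '%s'", f, type)
    }
    if (type == "fuzzy") {
      if (is.null(v$universe)) fpt_stop("variable '%s': fuzzy variables need a universe", f)
      lv <- linguistic_variable(f, as.numeric(unlist(v$universe)), v$sets,
                                units = v$units)
      if (length(lv$sets) < 2L) fpt_stop("variable '%s': needs >= 2 fuzzy sets", f)
      if (is.null(v$crisp_threshold) || !is_number(v$crisp_threshold)) {
        fpt_stop("variable '%s': fuzzy variables need a numeric 'crisp_threshold'", f)
      }
      vars[[f]] <- list(type = "fuzzy", linguistic = lv,
                        crisp_threshold = v$crisp_threshold, units = v$units)
    } else {
      vars[[f]] <- list(type = type, values = if (!is.null(v$values)) as.character(unlist(v$values)))
    }
  }
  structure(list(feature_order = feature_order, target = target,
                 positive_class = as.character(positive_class),
                 negative_class = as.character(negative_class),
                 variables = vars, threshold = threshold),
            class = "fpt_config")
}

fuzzy_variables <- function(config) {
  names(config$variables)[vapply(config$variables, function(v) v$type == "fuzzy", logical(1))]
}

#' @export
print.fpt_config <- function(x, ...) {
  cat(sprintf("FPT model configuration: %d features, target '%s' (positive: %s)\n",
              length(x$feature_order), x$target, x$positive_class))
  for (f in x$feature_order) {
    v <- x$variables[[f]]
    if (v$type == "fuzzy") {
      cat(sprintf("  %-14s fuzzy (%s; crisp cut %g)\n", f,
                  paste(names(v$linguistic$sets), collapse = "/"), v$crisp_threshold))
    } else {
      cat(sprintf("  %-14s %s\n", f, v$type))
    }
  }
  cat(sprintf("  default threshold: %g\n", x$threshold))
  invisible(x)
}

# ---- config file I/O ----------------------------------------------------

config_to_list <- function(config) {
  vars <- lapply(config$variables, function(v) {
    if (v$type == "fuzzy") {
      lv <- v$linguistic
      out <- list(type = "fuzzy", universe = as.numeric(lv$universe),
                  crisp_threshold = v$crisp_threshold,
                  sets = lapply(unname(lv$sets), function(s) {
                    list(name = s$name,
                         knots = lapply(seq_len(nrow(s$knots)),
                                        function(i) as.numeric(s$knots[i, ])))
                  }))
      if (!is.null(lv$units)) out$units <- lv$units
      out
    } else {
      out <- list(type = v$type)
      if (!is.null(v$values)) out$values <- as.list(v$values)
      out
    }
  })
  list(feature_order = as.list(config$feature_order), target = config$target,
       positive_class = config$positive_class, negative_class = config$negative_class,
       threshold = config$threshold, variables = vars)
}

config_from_list <- function(lst) {
  known <- c("feature_order", "target", "positive_class", "negative_class",
             "threshold", "variables")
  extra <- setdiff(names(lst), known)
  if (length(extra)) fpt_stop("unknown configuration key(s): %s", paste(extra, collapse = ", "))
  if (is.null(lst$target)) fpt_stop("configuration is missing 'target'")
  vars <- lapply(lst$variables, function(v) {
    if (identical(v$type, "fuzzy")) {
      v$sets <- lapply(v$sets, function(s) {
        fuzzy_set(s$name, lapply(s$knots, function(k) as.numeric(unlist(k))))
      })
    }
    v
  })
  fpt_config(
    feature_order = unlist(lst$feature_order),
    target = lst$target,
    positive_class = lst$positive_class %||% fpt_stop("configuration is missing 'positive_class'"),
    negative_class = lst$negative_class %||% fpt_stop("configuration is missing 'negative_class'"),
    variables = vars,
    threshold = lst$threshold %||% 0.5
  )
}

#' Read and write model configurations
#'
#' Configurations are stored as YAML (human-edited; JSON is also accepted on
#' read, chosen by file extension on write). All invariants are validated on
#' load with messages naming the offending field.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param config An `fpt_config`.
#' @return `load_config` returns an `fpt_config`; `save_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) fpt_stop("configuration file '%s' does not exist", path)
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(lst)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "fpt_config"))
  lst <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

# ---- discretization and fitting -----------------------------------------

#' Discretize fuzzy-numeric columns into linguistic terms
#'
#' Replaces each fuzzy variable's raw numeric column by the term label its
#' crisp threshold assigns (values at or above the threshold go to the rising
#' set). The tree itself stores only discrete statements, so this runs before
#' induction.
#'
#' @param records A data.frame.
#' @param config An `fpt_config`.
#' @return The data.frame with fuzzy columns replaced by term labels.
#' @export
discretize_records <- function(records, config) {
  stopifnot(is.data.frame(records), inherits(config, "fpt_config"))
  for (f in fuzzy_variables(config)) {
    if (!f %in% names(records)) next
    col <- records[[f]]
    if (!is.numeric(col)) {
      # already termed: accept term labels verbatim
      lv <- config$variables[[f]]$linguistic
      bad <- setdiff(unique(as.character(col)), names(lv$sets))
      if (length(bad)) {
        fpt_stop("variable '%s': values %s are neither numeric nor declared terms",
                 f, paste(bad, collapse = ", "))
      }
      next
    }
    v <- config$variables[[f]]
    records[[f]] <- crisp_assign(v$linguistic, col, v$crisp_threshold)
  }
  records
}

#' Fit a fuzzy probability tree model
#'
#' Discretizes the fuzzy columns and induces the probability tree over the
#' configured feature order. The returned model bundles the tree with its
#' configuration, which is what prediction, counterfactual queries and
#' serialization operate on.
#'
#' @param records Training records (data.frame; no missing values in used
#'   columns).
#' @param config An `fpt_config`.
#' @return An object of class `fpt_model` with fields `tree` and `config`.
#' @export
fpt_fit <- function(records, config) {
  stopifnot(inherits(config, "fpt_config"))
  disc <- discretize_records(records, config)
  tree <- build_tree(disc, config$feature_order, config$target,
                     class_levels = sort(c(config$positive_class, config$negative_class)))
  structure(list(tree = tree, config = config), class = "fpt_model")
}

#' @export
print.fpt_model <- function(x, ...) {
  cat("Fuzzy probability tree model\n")
  print(x$tree)
  fz <- fuzzy_variables(x$config)
  cat(sprintf("  fuzzy variables: %s\n",
              if (length(fz)) paste(fz, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Read and write fitted models as JSON
#'
#' @param model An `fpt_model`.
#' @param path File path.
#' @return `read_model` returns an `fpt_model`; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fpt_model"))
  jsonlite::write_json(
    list(format = "fptree/model", version = 1L,
         config = config_to_list(model$config), tree = tree_to_list(model$tree)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lst <- jsonlite::read_json(path)
  if (!identical(lst$format, "fptree/model")) fpt_stop("'%s' is not an fptree model file", path)
  structure(list(tree = tree_from_list(lst$tree),
                 config = config_from_list(lst$config)),
            class = "fpt_model")
}
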