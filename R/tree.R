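#' Build a probability tree from tabular records
#'
#' Induces a discrete probability tree over a fixed, expert-chosen feature
#' order. Each node splits on the next feature in `feature_order`; each
#' transition carries the empirical conditional relative frequency of the
#' child's statement given the parent path. Branches with zero support are
#' absent. Leaves (at depth `length(feature_order)`) hold per-class counts of
#' the binary target.
#'
#' Continuous features must be discretized before induction (crisply, or into
#' linguistic terms via [discretize_records()]); the tree stores only discrete
#' statements.
#'
#' @param records A data.frame with one row per case; feature columns may be
#'   text categories or 0/1 binaries (coerced to character); no missing values
#'   are allowed in used columns.
#' @param feature_order Character vector of feature names, root to leaf.
#' @param target Name of the binary class column.
#' @param class_levels Optional explicit class levels (length 2). Defaults to
#'   the sorted unique values observed in `records[[target]]`.
#' @return An object of class `fpt_tree` with fields `root`, `feature_order`,
#'   `target`, `class_levels`, `record_count` and `levels` (observed value set
#'   per feature).
#' @examples
#' d <- data.frame(x = c("a", "a", "b"), y = c("0", "1", "1"), cls = c("0", "0", "1"))
#' tr <- build_tree(d, c("x", "y"), "cls")
#' realizations(tr)
#' @export
build_tree <- function(records, feature_order, target, class_levels = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    fpt_stop("'records' must be a nonempty data.frame")
  }
  feature_order <- as.character(feature_order)
  if (length(feature_order) == 0L) fpt_stop("'feature_order' must be nonempty")
  missing_cols <- setdiff(c(feature_order, target), names(records))
  if (length(missing_cols)) {
    fpt_stop("unknown feature name(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (target %in% feature_order) fpt_stop("target '%s' cannot appear in feature_order", target)

  cols <- lapply(records[c(feature_order, target)], as.character)
  if (any(vapply(cols, anyNA, logical(1)))) {
    bad <- names(cols)[vapply(cols, anyNA, logical(1))]
    fpt_stop("missing values in column(s): %s (only complete records can be used)",
             paste(bad, collapse = ", "))
  }
  y <- cols[[target]]
  observed <- sort(unique(y))
  if (is.null(class_levels)) class_levels <- observed
  class_levels <- as.character(class_levels)
  if (length(class_levels) > 2L) {
    fpt_stop("target '%s' must be binary; found levels: %s", target,
             paste(class_levels, collapse = ", "))
  }
  if (!all(observed %in% class_levels)) {
    fpt_stop("target values %s outside declared class levels",
             paste(setdiff(observed, class_levels), collapse = ", "))
  }

  counter <- new.env(parent = emptyenv())
  counter$id <- 0L

  build_node <- function(idx, depth, path) {
    id <- counter$id
    counter$id <- counter$id + 1L
    if (depth == length(feature_order)) {
      cc <- vapply(class_levels, function(lv) sum(y[idx] == lv), numeric(1))
      return(list(id = id, statements = path, transitions = NULL,
                  class_counts = cc, counts = cc))
    }
    f <- feature_order[depth + 1L]
    vals <- sort(unique(cols[[f]][idx]))
    transitions <- vector("list", length(vals))
    counts <- stats::setNames(numeric(length(class_levels)), class_levels)
    for (k in seq_along(vals)) {
      sub <- idx[cols[[f]][idx] == vals[k]]
      child <- build_node(sub, depth + 1L, c(path, stats::setNames(vals[k], f)))
      transitions[[k]] <- list(theta = length(sub) / length(idx), child = child)
      counts <- counts + child$counts
    }
    list(id = id, statements = path, transitions = transitions,
         class_counts = NULL, counts = counts)
  }

  root <- build_node(seq_len(nrow(records)), 0L, stats::setNames(character(0), character(0)))
  structure(
    list(root = root, feature_order = feature_order, target = target,
         class_levels = class_levels, record_count = nrow(records),
         levels = lapply(cols[feature_order], function(v) sort(unique(v)))),
    class = "fpt_tree"
  )
}

is_leaf <- function(node) is.null(node$transitions)

# Feature that the children of `node` split on (NULL at a leaf).
node_split_variable <- function(tree, node) {
  if (is_leaf(node)) return(NULL)
  tree$feature_order[length(node$statements) + 1L]
}

# Locate a node by id; error if absent.
find_node <- function(tree, id) {
  walk <- function(node) {
    if (node$id == id) return(node)
    for (tr in node$transitions) {
      hit <- walk(tr$child)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  node <- walk(tree$root)
  if (is.null(node)) fpt_stop("node id %s not found in tree", format(id))
  node
}

#' Enumerate the total realizations of a probability tree
#'
#' A total realization is a root-to-leaf path; its probability is the product
#' of the transition probabilities along the path. Realization probabilities
#' sum to 1.
#'
#' @param tree An `fpt_tree`.
#' @return A data.frame with one row per leaf: one character column per
#'   feature, `prob` (path probability), `n` (training records at the leaf),
#'   and one `n_<class>` count column per class level.
#' @export
realizations <- function(tree) {
  stopifnot(inherits(tree, "fpt_tree"))
  rows <- list()
  walk <- function(node, prob) {
    if (is_leaf(node)) {
      rows[[length(rows) + 1L]] <<- c(
        as.list(node$statements),
        list(prob = prob, n = sum(node$class_counts)),
        stats::setNames(as.list(node$class_counts),
                        paste0("n_", names(node$class_counts)))
      )
      return(invisible())
    }
    for (tr in node$transitions) walk(tr$child, prob * tr$theta)
  }
  walk(tree$root, 1)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Validate a crisp condition list against the tree; returns named character.
check_conditions <- function(tree, conditions) {
  conditions <- as_statement_list(conditions)
  if (length(conditions) == 0L) return(character(0))
  unknown <- setdiff(names(conditions), tree$feature_order)
  if (length(unknown)) {
    fpt_stop("unknown variable(s) in conditions: %s", paste(unknown, collapse = ", "))
  }
  vapply(conditions, as.character, character(1))
}

#' Conditional class probability from a probability tree
#'
#' Computes `P(target = cls | conditions)` from the class counts of all leaves
#' whose realization satisfies every condition. With no conditions, returns
#' the marginal class prior.
#'
#' @param tree An `fpt_tree`.
#' @param conditions Statements (named list/vector, `fpt_statement` list, or
#'   empty) over variables in `feature_order`.
#' @param cls A class level of the target.
#' @return A probability.
#' @section Errors: conditions matched by zero training records raise an error
#'   of class `fptree_unsupported_query`; callers should fall back via
#'   [find_existing_conditions()].
#' @export
conditional_probability <- function(tree, conditions, cls) {
  stopifnot(inherits(tree, "fpt_tree"))
  cls <- as.character(cls)
  if (!cls %in% tree$class_levels) fpt_stop("unknown class label '%s'", cls)
  cond <- check_conditions(tree, conditions)

  total <- 0
  hit <- 0
  walk <- function(node) {
    # prune: a fixed-order chain lets us test conditions level by level
    if (length(node$statements)) {
      v <- names(node$statements)[length(node$statements)]
      if (v %in% names(cond) && node$statements[[v]] != cond[[v]]) return(invisible())
    }
    if (is_leaf(node)) {
      total <<- total + sum(node$class_counts)
      hit <<- hit + node$class_counts[[cls]]
      return(invisible())
    }
    for (tr in node$transitions) walk(tr$child)
  }
  walk(tree$root)
  if (total == 0) {
    stop(errorCondition(
      sprintf("conditions {%s} are matched by zero training records",
              paste(names(cond), cond, sep = "=", collapse = ", ")),
      class = c("fptree_unsupported_query", "fptree_error")
    ))
  }
  hit / total
}

#' Probability of an event
#'
#' Sums the probabilities of all total realizations satisfying an event
#' expression (see [event_is()] and the overloaded `!`, `&`, `|`).
#'
#' @param tree An `fpt_tree`.
#' @param event An `fpt_event`.
#' @return A probability.
#' @export
event_probability <- function(tree, event) {
  stopifnot(inherits(tree, "fpt_tree"), inherits(event, "fpt_event"))
  atoms <- event_atoms(event)
  vars <- vapply(atoms, `[[`, character(1), "variable")
  unknown <- setdiff(vars, tree$feature_order)
  if (length(unknown)) {
    fpt_stop("event references unknown variable(s): %s", paste(unknown, collapse = ", "))
  }
  p <- 0
  walk <- function(node, prob) {
    if (is_leaf(node)) {
      if (event_holds(event, node$statements)) p <<- p + prob
      return(invisible())
    }
    for (tr in node$transitions) walk(tr$child, prob * tr$theta)
  }
  walk(tree$root, 1)
  p
}

#' @export
print.fpt_tree <- function(x, ...) {
  n_leaves <- nrow(realizations(x))
  cat(sprintf("Probability tree over %d features (%s)\n",
              length(x$feature_order), paste(x$feature_order, collapse = " > ")))
  cat(sprintf("  target: %s (classes: %s); %d records in %d represented realizations\n",
              x$target, paste(x$class_levels, collapse = "/"),
              x$record_count, n_leaves))
  invisible(x)
}

# ---- serialization ------------------------------------------------------

node_to_list <- function(node) {
  out <- list(id = node$id,
              statements = as.list(node$statements))
  if (is_leaf(node)) {
    out$class_counts <- as.list(node$class_counts)
  } else {
    out$transitions <- lapply(node$transitions, function(tr) {
      list(theta = tr$theta, child = node_to_list(tr$child))
    })
  }
  out
}

node_from_list <- function(lst, class_levels) {
  statements <- vapply(lst$statements, as.character, character(1))
  if (!is.null(lst$class_counts)) {
    cc <- vapply(lst$class_counts, as.numeric, numeric(1))
    cc <- cc[class_levels[class_levels %in% names(cc)]]
    miss <- setdiff(class_levels, names(cc))
    if (length(miss)) cc[miss] <- 0
    cc <- cc[class_levels]
    return(list(id = lst$id, statements = statements, transitions = NULL,
                class_counts = cc, counts = cc))
  }
  kids <- lapply(lst$transitions, function(tr) {
    list(theta = tr$theta, child = node_from_list(tr$child, class_levels))
  })
  counts <- Reduce(`+`, lapply(kids, function(tr) tr$child$counts))
  list(id = lst$id, statements = statements, transitions = kids,
       class_counts = NULL, counts = counts)
}

tree_to_list <- function(tree) {
  list(format = "fptree/tree", version = 1L,
       feature_order = tree$feature_order, target = tree$target,
       class_levels = tree$class_levels, record_count = tree$record_count,
       levels = tree$levels, root = node_to_list(tree$root))
}

tree_from_list <- function(lst) {
  class_levels <- vapply(lst$class_levels, as.character, character(1))
  structure(
    list(root = node_from_list(lst$root, class_levels),
         feature_order = vapply(lst$feature_order, as.character, character(1)),
         target = lst$target, class_levels = class_levels,
         record_count = as.integer(lst$record_count),
         levels = lapply(lst$levels, function(v) vapply(v, as.character, character(1)))),
    class = "fpt_tree"
  )
}

#' Read and write probability trees as JSON
#'
#' The JSON document mirrors the node tuple (id, statements, transitions with
#' thetas, leaf class counts) and round-trips losslessly.
#'
#' @param tree An `fpt_tree`.
#' @param path File path.
#' @return `read_tree` returns an `fpt_tree`; `write_tree` returns `path`
#'   invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "fpt_tree"))
  jsonlite::write_json(tree_to_list(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  lst <- jsonlite::read_json(path)
  if (!identical(lst$format, "fptree/tree")) fpt_stop("'%s' is not an fptree tree file", path)
  tree_from_list(lst)
}

#' Export a probability tree to GraphViz DOT
#'
#' One graph node per tree node; edge labels give the transition probability
#' to 3 decimals. Leaf labels include the class counts.
#'
#' @param tree An `fpt_tree`.
#' @param path Optional file path; if `NULL` the DOT source is returned as a
#'   character string.
#' @return The DOT source, invisibly when written to a file.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "fpt_tree"))
  lines <- c("digraph fptree {", "  node [shape=box, fontname=\"Helvetica\"];")
  walk <- function(node) {
    label <- if (length(node$statements) == 0L) {
      "root"
    } else {
      v <- names(node$statements)[length(node$statements)]
      sprintf("%s IS %s", v, node$statements[[v]])
    }
    if (is_leaf(node)) {
      cc <- paste(names(node$class_counts), node$class_counts, sep = ": ", collapse = ", ")
      label <- sprintf("%s\\n[%s]", label, cc)
    }
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", node$id, label))
    for (tr in node$transitions) {
      lines <<- c(lines, sprintf("  n%d -> n%d [label=\"%.3f\"];",
                                 node$id, tr$child$id, tr$theta))
      walk(tr$child)
    }
  }
  walk(tree$root)
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}
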