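#' Fuzzy sets with piecewise-linear membership functions
#'
#' A fuzzy set represents a linguistic term (e.g. "Large Nodule") over a
#' numeric universe of discourse. Its membership function is piecewise linear
#' through the given knots and constant at the boundary memberships outside
#' the knot range, so every finite value receives a degree in \[0, 1\].
#'
#' @param name Linguistic term label.
#' @param knots A two-column matrix/data.frame (value, membership), or a list
#'   of `c(value, membership)` pairs. Knot values must be strictly increasing;
#'   memberships must lie in \[0, 1\].
#' @return An object of class `fpt_fuzzy_set`.
#' @examples
#' large <- fuzzy_set("LargeNodule", rbind(c(10, 0), c(20, 1)))
#' membership(large, 18) # 0.8
#' @export
fuzzy_set <- function(name, knots) {
  if (!is_string(name)) fpt_stop("fuzzy set 'name' must be a single string")
  if (is.list(knots) && !is.data.frame(knots)) knots <- do.call(rbind, knots)
  knots <- as.matrix(knots)
  if (ncol(knots) != 2L || nrow(knots) < 1L || !is.numeric(knots) || anyNA(knots)) {
    fpt_stop("fuzzy set '%s': knots must be a numeric (value, membership) table", name)
  }
  x <- knots[, 1]
  mu <- knots[, 2]
  if (is.unsorted(x, strictly = TRUE)) {
    fpt_stop("fuzzy set '%s': knot values must be strictly increasing", name)
  }
  if (any(mu < 0 | mu > 1)) {
    fpt_stop("fuzzy set '%s': knot memberships must lie in [0, 1]", name)
  }
  structure(list(name = name, knots = cbind(value = x, membership = mu)),
            class = "fpt_fuzzy_set")
}

#' Membership degree of a value in a fuzzy set
#'
#' Linear interpolation between bracketing knots, clamped to the boundary
#' memberships outside the knot range (out-of-universe values clamp; no
#' error).
#'
#' @param set An `fpt_fuzzy_set`.
#' @param value Numeric vector of values in universe units.
#' @return Membership degrees in \[0, 1\], one per value.
#' @export
membership <- function(set, value) {
  stopifnot(inherits(set, "fpt_fuzzy_set"))
  if (!is.numeric(value) || any(!is.finite(value))) {
    fpt_stop("membership values must be finite numbers")
  }
  k <- set$knots
  if (nrow(k) == 1L) return(rep(k[1, 2], length(value)))
  stats::approx(k[, 1], k[, 2], xout = value, rule = 2)$y
}

#' Complement of a fuzzy set
#'
#' Returns the fuzzy set with membership `1 - mu` at every knot, used to
#' auto-complete binary partitions when only one set of a pair is declared.
#'
#' @param set An `fpt_fuzzy_set`.
#' @param name Name for the complement (default `"Not<name>"`).
#' @return An `fpt_fuzzy_set`.
#' @export
complement_set <- function(set, name = paste0("Not", set$name)) {
  stopifnot(inherits(set, "fpt_fuzzy_set"))
  fuzzy_set(name, cbind(set$knots[, 1], 1 - set$knots[, 2]))
}

#' @export
print.fpt_fuzzy_set <- function(x, ...) {
  cat(sprintf("Fuzzy set '%s' (%d knots: %s)\n", x$name, nrow(x$knots),
              paste(sprintf("%g->%g", x$knots[, 1], x$knots[, 2]), collapse = ", ")))
  invisible(x)
}

#' Linguistic variables
#'
#' A linguistic variable maps a numeric feature to a partition of fuzzy sets,
#' one per tree branch value. When a single set is supplied, its complement
#' (membership `1 - mu`) is generated automatically so that the binary
#' partition sums to 1 everywhere.
#'
#' @param name Underlying numeric feature name.
#' @param universe Numeric `c(min, max)` of admissible values, in feature
#'   units.
#' @param sets A list of `fpt_fuzzy_set` (or a single set).
#' @param units Optional unit label (years, mm, mg/dL, ...), documentation
#'   only.
#' @return An object of class `fpt_linguistic_variable`.
#' @export
linguistic_variable <- function(name, universe, sets, units = NULL) {
  if (!is_string(name)) fpt_stop("linguistic variable 'name' must be a single string")
  if (!is.numeric(universe) || length(universe) != 2L || universe[1] >= universe[2]) {
    fpt_stop("variable '%s': universe must be c(min, max) with min < max", name)
  }
  if (inherits(sets, "fpt_fuzzy_set")) sets <- list(sets)
  if (!is.list(sets) || !length(sets) ||
      !all(vapply(sets, inherits, logical(1), "fpt_fuzzy_set"))) {
    fpt_stop("variable '%s': 'sets' must be a list of fuzzy_set objects", name)
  }
  if (length(sets) == 1L) sets <- c(sets, list(complement_set(sets[[1]])))
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) fpt_stop("variable '%s': duplicated set names", name)
  for (s in sets) {
    if (any(s$knots[, 1] < universe[1] - 1e-9) || any(s$knots[, 1] > universe[2] + 1e-9)) {
      fpt_stop("variable '%s': knots of set '%s' fall outside the universe [%g, %g]",
               name, s$name, universe[1], universe[2])
    }
  }
  structure(list(name = name, universe = universe,
                 sets = stats::setNames(sets, nms), units = units),
            class = "fpt_linguistic_variable")
}

#' @export
print.fpt_linguistic_variable <- function(x, ...) {
  cat(sprintf("Linguistic variable '%s' on [%g, %g]%s; terms: %s\n",
              x$name, x$universe[1], x$universe[2],
              if (is.null(x$units)) "" else paste0(" ", x$units),
              paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

#' Branch traversal weights for a raw value
#'
#' Evaluates every set of a linguistic variable at a raw value and
#' renormalizes the degrees to sum to 1, so they can weight the branches of a
#' fuzzy split during tree traversal. Degrees that already form a partition
#' of unity (the binary-partition case) are unchanged by renormalization.
#'
#' @param var An `fpt_linguistic_variable`.
#' @param value A finite number in universe units.
#' @return Named numeric vector of weights (one per set) summing to 1.
#' @section Errors: a value with zero membership in every set (outside every
#'   set's support) raises an error.
#' @export
branch_weights <- function(var, value) {
  stopifnot(inherits(var, "fpt_linguistic_variable"))
  if (!is_number(value)) fpt_stop("'value' must be a single finite number")
  w <- vapply(var$sets, membership, numeric(1), value = value)
  s <- sum(w)
  if (s <= 0) {
    fpt_stop("value %g of '%s' has zero membership in every set", value, var$name)
  }
  w / s
}

# Which set a crisp threshold assigns: values >= threshold go to the "rising"
# set (the one with the larger membership at the universe's upper end).
crisp_assign <- function(var, value, threshold) {
  stopifnot(inherits(var, "fpt_linguistic_variable"))
  if (length(var$sets) != 2L) {
    fpt_stop("crisp thresholds are defined for binary partitions only ('%s' has %d sets)",
             var$name, length(var$sets))
  }
  hi <- vapply(var$sets, membership, numeric(1), value = var$universe[2])
  rising <- names(var$sets)[which.max(hi)]
  falling <- setdiff(names(var$sets), rising)
  ifelse(value >= threshold, rising, falling)
}
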