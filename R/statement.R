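#' Statements: "variable IS value"
#'
#' A statement is the atom of probability-tree paths and patient descriptions:
#' an assertion that a variable takes one of its admissible discrete values
#' (a category label, a binary level, or a linguistic term).
#'
#' @param variable Feature name (single string).
#' @param value The asserted value. Coerced to character for crisp values;
#'   numeric values are kept numeric, signalling a raw measurement that a
#'   linguistic variable will fuzzify at prediction time.
#' @return An object of class `fpt_statement` with fields `variable`, `value`.
#' @examples
#' statement("gender", "Female")
#' statement("nodule_mm", 18) # raw value for a fuzzy variable
#' @export
statement <- function(variable, value) {
  if (!is_string(variable)) fpt_stop("'variable' must be a single string")
  if (length(value) != 1L || is.na(value)) {
    fpt_stop("statement value for '%s' must be a single non-missing value", variable)
  }
  if (!is.numeric(value)) value <- as.character(value)
  structure(list(variable = variable, value = value), class = "fpt_statement")
}

#' @export
print.fpt_statement <- function(x, ...) {
  cat(sprintf("<%s IS %s>\n", x$variable, format(x$value)))
  invisible(x)
}

# Normalise the many user-facing statement spellings into one internal shape:
# a named list, one entry per variable, values character (crisp) or numeric
# (raw measurement for a fuzzy variable). Accepts a named list/vector, a list
# of fpt_statement, or a one-row data.frame.
as_statement_list <- function(x) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (inherits(x, "fpt_statement")) x <- list(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) fpt_stop("expected a single-row data.frame of statements")
    x <- as.list(x)
  }
  if (is.list(x) && length(x) && all(vapply(x, inherits, logical(1), "fpt_statement"))) {
    out <- lapply(x, `[[`, "value")
    names(out) <- vapply(x, `[[`, character(1), "variable")
    x <- out
  }
  if (is.atomic(x)) x <- as.list(x)
  if (is.null(names(x)) || any(names(x) == "")) {
    fpt_stop("statements must be named by variable")
  }
  if (anyDuplicated(names(x))) {
    fpt_stop("at most one statement per variable (duplicated: %s)",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  lapply(x, function(v) {
    if (length(v) != 1L || is.na(v)) fpt_stop("statement values must be single non-missing values")
    if (is.numeric(v)) v else as.character(v)
  })
}

#' Event expressions over tree realizations
#'
#' Events select sets of total realizations of a probability tree. An atomic
#' event asserts a single statement; composite events combine events with
#' negation, conjunction and disjunction. The Boolean operators `!`, `&`, `|`
#' are overloaded for event objects.
#'
#' @param variable,value The statement asserted by an atomic event.
#' @param e,e1,e2 Event expressions.
#' @return An object of class `fpt_event`.
#' @examples
#' e <- event_is("X", "A") & !event_is("Y", "1")
#' @seealso [event_probability()]
#' @export
event_is <- function(variable, value) {
  s <- statement(variable, value)
  structure(list(op = "atom", statement = s), class = "fpt_event")
}

#' @rdname event_is
#' @export
event_not <- function(e) {
  stopifnot(inherits(e, "fpt_event"))
  structure(list(op = "not", args = list(e)), class = "fpt_event")
}

#' @rdname event_is
#' @export
event_and <- function(e1, e2) {
  stopifnot(inherits(e1, "fpt_event"), inherits(e2, "fpt_event"))
  structure(list(op = "and", args = list(e1, e2)), class = "fpt_event")
}

#' @rdname event_is
#' @export
event_or <- function(e1, e2) {
  stopifnot(inherits(e1, "fpt_event"), inherits(e2, "fpt_event"))
  structure(list(op = "or", args = list(e1, e2)), class = "fpt_event")
}

#' @export
Ops.fpt_event <- function(e1, e2) {
  switch(.Generic,
    "!" = event_not(e1),
    "&" = event_and(e1, e2),
    "|" = event_or(e1, e2),
    fpt_stop("operator '%s' is not defined for events", .Generic)
  )
}

#' @export
print.fpt_event <- function(x, ...) {
  cat(deparse_event(x), "\n")
  invisible(x)
}

deparse_event <- function(e) {
  switch(e$op,
    atom = sprintf("(%s = %s)", e$statement$variable, format(e$statement$value)),
    not = sprintf("NOT %s", deparse_event(e$args[[1]])),
    and = sprintf("(%s AND %s)", deparse_event(e$args[[1]]), deparse_event(e$args[[2]])),
    or = sprintf("(%s OR %s)", deparse_event(e$args[[1]]), deparse_event(e$args[[2]]))
  )
}

# Evaluate an event against one total realization, given as a named character
# vector variable -> value.
event_holds <- function(e, values) {
  switch(e$op,
    atom = {
      v <- values[[e$statement$variable]]
      identical(v, as.character(e$statement$value))
    },
    not = !event_holds(e$args[[1]], values),
    and = event_holds(e$args[[1]], values) && event_holds(e$args[[2]], values),
    or = event_holds(e$args[[1]], values) || event_holds(e$args[[2]], values)
  )
}

# All atomic statements referenced by an event (for validation).
event_atoms <- function(e) {
  if (e$op == "atom") return(list(e$statement))
  do.call(c, lapply(e$args, event_atoms))
}
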