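#' What-if scenarios
#'
#' A scenario pairs a patient's factual evidence with a set of interventions
#' (statements replacing same-variable evidence, e.g. "had this patient taken
#' RASI medication") and a set of removed variables treated as unknown.
#'
#' @param evidence A [patient_record()], named statement list, or one-row
#'   data.frame.
#' @param interventions Named list/vector of replacement statements (raw
#'   numeric values allowed for fuzzy variables).
#' @param removed Character vector of variable names to treat as unknown.
#' @return An object of class `fpt_scenario`.
#' @export
scenario <- function(evidence, interventions = list(), removed = character(0)) {
  interventions <- as_statement_list(interventions)
  removed <- as.character(removed)
  overlap <- intersect(names(interventions), removed)
  if (length(overlap)) {
    fpt_stop("variable(s) %s cannot be both intervened on and removed",
             paste(overlap, collapse = ", "))
  }
  structure(list(evidence = evidence, interventions = interventions,
                 removed = removed), class = "fpt_scenario")
}

#' Counterfactual (scenario) query
#'
#' Re-evaluates a patient's class probability after substituting or removing
#' statements, returning the factual and scenario results side by side.
#' Semantics: substitution and re-traversal of the tree (observational
#' re-conditioning). Removed variables are handled by uniform child weighting
#' during traversal, so the scenario result remains a proper probability.
#'
#' @param model An `fpt_model`.
#' @param scen An [scenario()] (or a patient, for an identity scenario).
#' @param threshold Classification cut-off (default: configured).
#' @return An object of class `fpt_counterfactual`: a list with `factual` and
#'   `scenario` prediction rows (see [predict.fpt_model()]) and the scenario
#'   definition.
#' @export
counterfactual_query <- function(model, scen, threshold = NULL) {
  stopifnot(inherits(model, "fpt_model"))
  if (!inherits(scen, "fpt_scenario")) scen <- scenario(scen)
  config <- model$config
  evid <- patient_statements(scen$evidence, config)

  bad <- setdiff(c(names(scen$interventions), scen$removed), config$feature_order)
  if (length(bad)) {
    fpt_stop("intervention/removal on variable(s) absent from the tree: %s",
             paste(bad, collapse = ", "))
  }
  for (v in names(scen$interventions)) {
    val <- scen$interventions[[v]]
    cfgv <- config$variables[[v]]
    if (cfgv$type == "fuzzy") {
      if (!is.numeric(val)) {
        lv <- cfgv$linguistic
        if (!as.character(val) %in% names(lv$sets)) {
          fpt_stop("intervention value '%s' is not an admissible term of '%s'", val, v)
        }
      }
    } else if (!is.null(cfgv$values) && !as.character(val) %in% cfgv$values) {
      fpt_stop("intervention value '%s' is not admissible for '%s'", val, v)
    }
  }

  alt <- evid
  for (v in names(scen$interventions)) alt[[v]] <- scen$interventions[[v]]
  alt <- alt[setdiff(names(alt), scen$removed)]

  factual <- predict(model, evid, threshold = threshold)
  counterf <- predict(model, alt, threshold = threshold)
  structure(list(factual = factual, scenario = counterf, definition = scen),
            class = "fpt_counterfactual")
}

#' @export
print.fpt_counterfactual <- function(x, ...) {
  d <- x$definition
  cat("Counterfactual query\n")
  if (length(d$interventions)) {
    cat("  set:  ", paste(names(d$interventions),
                          vapply(d$interventions, format, character(1)),
                          sep = " = ", collapse = ", "), "\n")
  }
  if (length(d$removed)) cat("  unset:", paste(d$removed, collapse = ", "), "\n")
  cat(sprintf("  factual : P(positive) = %.4f  [label %s, support %d]\n",
              x$factual$prob_positive, x$factual$label, x$factual$support))
  cat(sprintf("  scenario: P(positive) = %.4f  [label %s, support %d]\n",
              x$scenario$prob_positive, x$scenario$label, x$scenario$support))
  invisible(x)
}
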