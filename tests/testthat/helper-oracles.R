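# Independent oracles: brute-force row filtering and exhaustive path
# enumeration, kept deliberately separate from the package's recursive
# implementations.

# P(target = cls | conditions) by filtering the raw training rows.
oracle_conditional <- function(records, conditions, target, cls) {
  keep <- rep(TRUE, nrow(records))
  for (v in names(conditions)) {
    keep <- keep & (as.character(records[[v]]) == as.character(conditions[[v]]))
  }
  if (!any(keep)) return(NA_real_)
  mean(as.character(records[[target]])[keep] == as.character(cls))
}

# P(event) as the fraction of raw training rows satisfying the event.
oracle_event <- function(records, event) {
  holds_row <- function(e, row) {
    switch(e$op,
      atom = identical(as.character(row[[e$statement$variable]]),
                       as.character(e$statement$value)),
      not = !holds_row(e$args[[1]], row),
      and = holds_row(e$args[[1]], row) && holds_row(e$args[[2]], row),
      or = holds_row(e$args[[1]], row) || holds_row(e$args[[2]], row)
    )
  }
  mean(vapply(seq_len(nrow(records)), function(i) holds_row(event, records[i, , drop = FALSE]),
              logical(1)))
}

# Exhaustive weighted path enumeration for the fuzzy traversal: walks every
# root-to-leaf path once, accumulating per-level weights by the stated rules,
# and sums weight * leaf class fraction over all leaves.
oracle_fuzzy_enum <- function(tree, stmts, cls, fuzzy = list()) {
  if (inherits(fuzzy, "fpt_config")) {
    fz <- names(fuzzy$variables)[vapply(fuzzy$variables, function(v) v$type == "fuzzy", logical(1))]
    fuzzy <- lapply(fuzzy$variables[fz], `[[`, "linguistic")
  }
  total <- 0
  walk <- function(node, weight) {
    if (is.null(node$transitions)) {
      frac <- node$class_counts[[as.character(cls)]] / sum(node$class_counts)
      total <<- total + weight * frac
      return(invisible())
    }
    f <- tree$feature_order[length(node$statements) + 1L]
    kids <- node$transitions
    vals <- vapply(kids, function(tr) tr$child$statements[[length(tr$child$statements)]],
                   character(1))
    w <- if (!f %in% names(stmts)) {
      rep(1 / length(kids), length(kids))
    } else {
      val <- stmts[[f]]
      if (is.numeric(val)) {
        bw <- branch_weights(fuzzy[[f]], val)[vals]
        bw[is.na(bw)] <- 0
        if (sum(bw) > 0) bw / sum(bw) else vapply(kids, `[[`, numeric(1), "theta")
      } else if (val %in% vals) {
        as.numeric(vals == val)
      } else {
        vapply(kids, `[[`, numeric(1), "theta")
      }
    }
    for (k in seq_along(kids)) {
      if (w[k] > 0) walk(kids[[k]]$child, weight * w[k])
    }
  }
  walk(tree$root, 1)
  unname(total)
}

# Brute-force largest represented condition subset: powerset search over the
# raw rows, maximum size, ties broken toward keeping earlier features.
oracle_largest_subset <- function(records, stmts, feature_order) {
  stmts <- stmts[intersect(feature_order, names(stmts))]
  k <- length(stmts)
  best <- NULL
  best_key <- NULL
  for (code in 0:(2^k - 1)) {
    keep <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    sub <- stmts[keep]
    ok <- TRUE
    if (length(sub)) {
      match_rows <- rep(TRUE, nrow(records))
      for (v in names(sub)) {
        match_rows <- match_rows & (as.character(records[[v]]) == as.character(sub[[v]]))
      }
      ok <- any(match_rows)
    }
    if (!ok) next
    # key: size first, then kept-pattern with earlier features preferred
    key <- c(sum(keep), as.numeric(keep))
    if (is.null(best_key) || lex_greater(key, best_key)) {
      best <- sub
      best_key <- key
    }
  }
  best
}

lex_greater <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1]] > b[d[1]]
}

# Random crisp fixture: categorical features with 2-3 levels, binary target.
random_fixture <- function(seed, n_features = 4, n_rows = 60) {
  withr::with_seed(seed, {
    feats <- paste0("f", seq_len(n_features))
    cols <- lapply(feats, function(f) {
      nlev <- sample(2:3, 1)
      sample(LETTERS[seq_len(nlev)], n_rows, replace = TRUE)
    })
    names(cols) <- feats
    cols$target <- as.character(stats::rbinom(n_rows, 1, 0.4))
    list(records = as.data.frame(cols, stringsAsFactors = FALSE),
         feature_order = feats)
  })
}

# A tiny two-fuzzy-variable config over features x (universe 0-10, cut 5)
# and z (universe 0-100, cut 50), for fuzzy fixtures.
toy_fuzzy_config <- function(feature_order = c("x", "g", "z"),
                             types = c(x = "fuzzy", g = "binary", z = "fuzzy")) {
  vars <- list(
    x = list(type = "fuzzy", universe = c(0, 10), crisp_threshold = 5,
             sets = list(fuzzy_set("HighX", rbind(c(2, 0), c(8, 1))))),
    g = list(type = "binary", values = c("a", "b")),
    z = list(type = "fuzzy", universe = c(0, 100), crisp_threshold = 50,
             sets = list(fuzzy_set("HighZ", rbind(c(30, 0), c(70, 1)))))
  )
  fpt_config(feature_order = feature_order, target = "target",
             positive_class = "1", negative_class = "0",
             variables = vars[feature_order], threshold = 0.5)
}

# Random fuzzy cohort rows for the toy config.
toy_fuzzy_rows <- function(seed, n = 80) {
  withr::with_seed(seed, {
    data.frame(
      x = stats::runif(n, 0, 10),
      g = sample(c("a", "b"), n, replace = TRUE),
      z = stats::runif(n, 0, 100),
      target = as.character(stats::rbinom(n, 1, 0.45)),
      stringsAsFactors = FALSE
    )
  })
}
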