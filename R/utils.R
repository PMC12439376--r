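# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so library functions never clobber a user's random stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Lightweight info-level logging; suppress with options(fptree.quiet = TRUE).
fpt_log <- function(fmt, ...) {
  if (!isTRUE(getOption("fptree.quiet", FALSE))) {
    message("[fptree] ", sprintf(fmt, ...))
  }
}

fpt_stop <- function(fmt, ..., class = "fptree_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fptree_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
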