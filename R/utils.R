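# Internal helpers shared across the package.

# User-facing errors (bad input, bad config, bad file) carry the
# "em_user_error" class so command wrappers can map them to exit code 2.
stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("em_user_error", "error")))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
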