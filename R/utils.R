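# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so that package functions never perturb the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

sigmoid <- function(z) 1 / (1 + exp(-z))

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
}
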