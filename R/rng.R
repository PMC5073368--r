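# Seed plumbing. All randomness in the package flows through explicit seeds;
# `local_seed` evaluates an expression under a seed without disturbing the
# caller's RNG stream, and `derive_seed` splits one user seed into
# independent per-stage seeds via a tagged integer hash.

#' Evaluate an expression under a temporary RNG seed
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`. The caller's `.Random.seed` is restored.
#' @export
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a sub-seed from a master seed and a stage tag
#'
#' Deterministic splitting scheme: the tag is hashed to an integer and mixed
#' with the master seed modulo 2^31 - 1, so every pipeline stage gets an
#' independent, reproducible stream from one user-facing seed.
#'
#' @param seed Master integer seed.
#' @param tag Character stage tag (e.g. `"scene"`, `"balance"`).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  x <- (x * 48271 + h * 16807) %% m
  x <- (x * 48271) %% m
  as.integer(max(1, x %% (m - 1)))
}
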