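## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## The caller's .Random.seed is restored afterwards so seeded package
## functions never perturb the user's stream. seed = NULL means "use the
## current stream" (no save/restore).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Average-rank transform (the tie convention used throughout).
rankAvg <- function(x) rank(x, ties.method = "average", na.last = "keep")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isBinaryAdjacency <- function(A) {
  is.matrix(A) && nrow(A) == ncol(A) &&
    all(A %in% c(0, 1)) &&
    all(A == t(A)) &&
    all(diag(A) == 0)
}
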