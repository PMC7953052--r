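# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Per-stage seeds derived from one user-facing seed; keeps every seed well
# inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

# Encode an unordered node pair (0-based ids) as one numeric key.  Exact for
# n_nodes^2 < 2^53, i.e. any graph this package targets.
pair_key <- function(u, v, n_nodes) {
  a <- pmin(u, v)
  b <- pmax(u, v)
  as.numeric(a) * n_nodes + b
}

`%||%` <- function(x, y) if (is.null(x)) y else x
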