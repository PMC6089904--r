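# Internal helpers shared across modules.

# Run code under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a per-cell stream seed below 2^31 from a root seed and cell indices.
derive_seed <- function(root, i, j = 0L) {
  (abs(as.numeric(root)) + 100003 * i + 10007 * j) %% 2147483646 + 1
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite and numeric", call. = FALSE)
  invisible(x)
}

# Canonical group ordering: numeric if all labels parse as numbers, else
# lexicographic. Makes fits invariant to record shuffling.
order_groups <- function(labels) {
  u <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}
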