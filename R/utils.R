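#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministically expand a top-level seed into per-stage seeds (< 2^31).
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
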