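# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer or NULL", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)) * 131L)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  if (x < min || (strict_min && x <= min) || x > max)
    stop(sprintf("%s out of range", name), call. = FALSE)
  as.numeric(x)
}
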