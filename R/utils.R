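# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so generators are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation: a master seed fans out to named streams
## (e.g. per participant x video, per bootstrap iteration) so stages can be
## re-run in isolation. Plain 32-bit LCG mixing over the seed and label hash;
## result is always a valid positive 32-bit seed.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(as.integer(seed)) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 69069 + code * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

stopifnot_scalar <- function(x, name, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
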