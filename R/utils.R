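## Internal helpers shared across modules.

## Derive a reproducible substream seed from a global seed and an integer
## or string key.  Counter-based so that adding taxa/stages does not
## perturb the streams of existing ones.  Result is in [1, 2^31 - 2].
substream_seed <- function(seed, key) {
  if (is.character(key)) {
    key <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  }
  ## all intermediates stay below 2^53, exact in doubles
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(key) * 40503
  as.integer(s %% 2147483629 + 1)
}

## Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Trapezoidal integral on an ordered grid.
trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
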