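# internal helpers

# run expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit sub-seed from a base seed and a stream index
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + 12345 * as.numeric(stream)) %% 2147483647
}

stopIf <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}
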