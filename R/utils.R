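# Run expr with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched. seed = NULL uses (and advances) the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stream index, kept below 2^31.
.childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}
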