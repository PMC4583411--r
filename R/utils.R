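# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of distinct child seeds from one master seed (kept within
# 32-bit integer range)
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
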