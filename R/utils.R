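## Internal helpers: classed conditions and RNG isolation.

bsdrError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bsdr_error")))
}

configError <- function(msg) bsdrError(msg, "bsdr_config_error")
dataError <- function(msg) bsdrError(msg, "bsdr_data_error")
trainingError <- function(msg) bsdrError(msg, "bsdr_training_error")

## Evaluate `expr` under a given seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Half-up rounding (R's round() is half-to-even).
roundHalfUp <- function(x) floor(x + 0.5)

## Split an index vector into two halves differing by at most one
## element; the second half receives the extra element when odd.
halves <- function(idx) {
  k <- length(idx)
  h <- k %/% 2L
  list(first = idx[seq_len(h)], second = idx[seq.int(h + 1L, k)])
}
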