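## Shared fixtures: everything is generated in code at test time.

## A tiny 4-sample x 6-band classification table on disk.
writeTinyTable <- function(path, sep = ",", labels = c("corn", "wheat",
                                                       "corn", "wheat"),
                           holeRow = NULL) {
  set.seed(42)
  m <- matrix(round(runif(24), 6), nrow = 4)
  df <- as.data.frame(m)
  names(df) <- paste0("b", 1:6)
  df$crop <- labels
  if (!is.null(holeRow)) df[holeRow, 2] <- NA
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}

## Small regression SpectralSet with planted bands, for fast training
## tests. Returns the generateSpectra() list.
smallRegression <- function(n = 400, L = 100,
                            planted = round(L * c(0.3, 0.7)),
                            smoothness = max(1, min(5, L %/% 4)),
                            noiseSd = 0.02, seed = 9) {
  generateSpectra(syntheticSpec(n, L, planted, task = "regression",
                                smoothness = smoothness,
                                noiseSd = noiseSd, seed = seed))
}

## An independent scalar linear-interpolation oracle, written as a plain
## loop so it shares no code path with the package implementation.
scalarInterpOracle <- function(v, q) {
  L <- length(v)
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    pos <- q[i] * (L - 1)
    lo <- floor(pos)
    hi <- min(lo + 1, L - 1)
    w <- pos - lo
    out[i] <- v[lo + 1] * (1 - w) + v[hi + 1] * w
  }
  out
}
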