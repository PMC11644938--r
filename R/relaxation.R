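#' Map a normalized band index to an integer band
#'
#' The relaxed search space is the unit interval: a normalized index
#' q in [0, 1] denotes a (fractional) position along the spectral axis.
#' The denormalization d(q) = floor(q * (L - 1)) + 1 maps it back to the
#' original 1-based integer band range, monotonically and onto
#' \{1, ..., L\}.
#'
#' @param q numeric vector of normalized indices in [0, 1].
#' @param L number of bands (>= 2).
#' @return integer band indices in 1..L.
#' @examples
#' denormalizeIndex(c(0, 0.5, 1), L = 131)  # 1, 66, 131
#' @export
denormalizeIndex <- function(q, L) {
  checkNormalized(q)
  if (L < 2L) configError("L must be at least 2")
  as.integer(floor(q * (L - 1)) + 1)
}

checkNormalized <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0 | q > 1))
    bsdrError("normalized indices must lie in [0, 1]", "bsdr_domain_error")
  invisible(q)
}

#' Piecewise-linear reflectance at a fractional band index
#'
#' Approximates one sample's reflectance at a fractional spectral
#' position by linear interpolation between the two bracketing bands:
#' B(q) = v[d(q)] + (v[d(q) + 1] - v[d(q)]) * (q*(L-1) - floor(q*(L-1))).
#' At q = 1 the bracket degenerates (d(q) = L); the second access is
#' clamped to v[L], which leaves the value unchanged because the
#' fractional multiplier is then exactly zero.
#'
#' Exact at grid points q = (j - 1)/(L - 1); between grid points the
#' derivative with respect to q is (v[d(q)+1] - v[d(q)]) * (L - 1),
#' which is what lets gradients flow into the band indices.
#'
#' @param v numeric reflectance vector of one sample (length L >= 2).
#' @param q numeric vector of normalized indices in [0, 1].
#' @return interpolated reflectance value(s), one per q.
#' @examples
#' interpolateReflectance(c(0, 1), 0.25)        # 0.25
#' interpolateReflectance(c(0.3, 0.5, 0.9), 1)  # 0.9
#' @export
interpolateReflectance <- function(v, q) {
  L <- length(v)
  if (L < 2L) configError("v must have at least 2 bands")
  checkNormalized(q)
  pos <- q * (L - 1)
  j <- floor(pos) + 1
  frac <- pos - (j - 1)
  jr <- pmin(j + 1, L)
  v[j] + (v[jr] - v[j]) * frac
}

#' Interpolate a batch of samples at a set of relaxed band indices
#'
#' Evaluates every sample's piecewise-linear interpolant at each of t
#' normalized indices, producing the N x t matrix fed to the inference
#' network. Also returns the per-entry slope d/dq (an N x t matrix),
#' used during backpropagation to route the loss gradient into the band
#' parameters. All samples share the same band grid, so each index
#' touches just two columns of X.
#'
#' @param X numeric N x L matrix, samples by bands.
#' @param r numeric vector of t normalized indices in [0, 1].
#' @return list with \code{values} (N x t) and \code{slopes} (N x t).
#' @export
interpolateBatch <- function(X, r) {
  L <- ncol(X)
  if (L < 2L) configError("X must have at least 2 band columns")
  checkNormalized(r)
  N <- nrow(X)
  t_ <- length(r)
  vals <- matrix(0, N, t_)
  slopes <- matrix(0, N, t_)
  pos <- r * (L - 1)
  j <- as.integer(floor(pos) + 1)
  frac <- pos - (j - 1)
  jr <- pmin(j + 1L, L)
  for (p in seq_len(t_)) {
    gap <- X[, jr[p]] - X[, j[p]]
    vals[, p] <- X[, j[p]] + gap * frac[p]
    slopes[, p] <- gap * (L - 1)
  }
  list(values = vals, slopes = slopes)
}
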