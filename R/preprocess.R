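#' Remove likely false-positive regions (background filtering)
#'
#' Regions whose epigenetic vector consists mainly of -1's carry essentially
#' no mark signal and are very likely false positives of the upstream region
#' caller. A vector is removed when its [dotsim()] with the negative-ones
#' vector is at least `threshold` (boundary inclusive: a length-10 vector
#' with nine -1 entries scores exactly 0.8 and is removed under the default).
#' All-zero vectors, which can only arise from degenerate inputs, have an
#' undefined norm and are dropped with a warning.
#'
#' @param x an `epivectors` object or plain matrix (rows = vectors).
#' @param threshold similarity cutoff in (0, 1\] (default 0.8).
#' @return the retained rows, in their original order, with metadata intact.
#' @export
filter_background <- function(x, threshold = 0.8) {
  stopifnot(is.matrix(x), threshold > 0, threshold <= 1)
  norms <- sqrt(rowSums(x^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero vector(s) removed (undefined norm)")
  }
  # norm product under a single sqrt so the exact 0.8 boundary of integer
  # +/-1 vectors is not blurred by floating-point rounding
  sims <- ifelse(zero, Inf, -rowSums(x) / sqrt(rowSums(x^2) * ncol(x)))
  keep <- sims < threshold
  out <- x[keep, , drop = FALSE]
  if (inherits(x, "epivectors")) out <- .restamp(out, x) else out
}

#' Entry-wise consensus of a vector with two references
#'
#' The denoising primitive: an entry survives only when it agrees with the
#' corresponding entry of both reference vectors; disagreements are set to 0.
#' For example `c(1, 1, -1)` against references `c(1, -1, -1)` and
#' `c(1, -1, -1)` gives `c(1, 0, -1)`.
#'
#' @param v vector to denoise.
#' @param r1,r2 reference vectors of the same length.
#' @return vector of the same length with entries in \{-1, 0, +1\}.
#' @export
consensus_entries <- function(v, r1, r2) {
  stopifnot(length(v) == length(r1), length(v) == length(r2))
  ifelse(v == r1 & v == r2, v, 0)
}

#' Consensus denoising of an epigenetic-vector set
#'
#' Each vector is compared with two other vectors drawn uniformly at random
#' (two distinct indices, excluding the vector itself) from the same set;
#' entries that do not agree across all three are zeroed via
#' [consensus_entries()]. Reference draws are independent per vector and
#' reproducible under `seed`. Sets with fewer than three vectors pass through
#' unchanged with a warning.
#'
#' @param x an `epivectors` object or matrix with entries in \{-1, +1\}.
#' @param seed integer RNG seed.
#' @return denoised set of the same dimensions, entries in \{-1, 0, +1\}.
#' @export
denoise_vectors <- function(x, seed = 1L) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 3) {
    warning("fewer than 3 vectors; denoising skipped")
    return(x)
  }
  out <- withr::with_seed(seed, {
    res <- x
    for (i in seq_len(n)) {
      pool <- seq_len(n)[-i]
      refs <- pool[sample.int(n - 1L, 2L)]
      res[i, ] <- consensus_entries(x[i, ], x[refs[1L], ], x[refs[2L], ])
    }
    res
  })
  if (inherits(x, "epivectors")) .restamp(out, x) else out
}
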