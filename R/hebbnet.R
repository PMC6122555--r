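#' Symmetric saturating linear transfer function
#'
#' Clips componentwise to \[-1, +1\]: `+1` for `x >= 1`, `x` itself on the
#' open interval `(-1, 1)`, `-1` for `x <= -1`. This keeps every network
#' response on the same scale as the +/-1 epigenetic vectors.
#'
#' @param x numeric scalar, vector or matrix.
#' @return same shape as `x`, values in \[-1, 1\].
#' @examples
#' satlins(c(2.3, 0.4, -2.2))
#' @export
satlins <- function(x) {
  pmin(pmax(x, -1), 1)
}

#' Response of the Hebbian network to a pair of stimuli
#'
#' The unconditioned stimulus `b` is an epigenetic vector; the conditioned
#' stimulus `p` is the ones vector. The response is
#' `satlins(b + w * p)`: the clipped sum of the stimulus and the prototype
#' learned so far. With an all-zero `b` the response is the prototype itself,
#' which is what makes the trained network recall its signature on the
#' conditioned stimulus alone.
#'
#' @param b unconditioned stimulus (entries in \{-1, 0, +1\}).
#' @param w weight / prototype vector.
#' @param p conditioned stimulus; defaults to the ones vector and there is no
#'   reason to pass anything else.
#' @return response vector, entries in \[-1, 1\].
#' @export
hebb_response <- function(b, w, p = rep(1, length(w))) {
  if (length(b) != length(w) || length(p) != length(w)) {
    stop("b, w and p must have equal lengths")
  }
  satlins(b + w * p)
}

#' One unsupervised Hebbian weight update
#'
#' `w' = w + alpha * (a(b, w, p) - w) * p` with `a` from [hebb_response()].
#' Since the response is bounded in \[-1, 1\] and `w'` is a convex
#' combination of `w` and the response (for `p = 1`), weights started inside
#' \[-1, 1\] can never leave it. `alpha` is both the learning and the decay
#' rate: each presentation moves the prototype a small step toward the
#' response to the current stimulus pair.
#'
#' @inheritParams hebb_response
#' @param alpha learning rate in (0, 1\].
#' @return updated weight vector.
#' @export
hebb_update <- function(w, b, p = rep(1, length(w)), alpha = 0.1) {
  stopifnot(alpha > 0, alpha <= 1)
  if (length(b) != length(w) || length(p) != length(w)) {
    stop("b, w and p must have equal lengths")
  }
  w + alpha * (hebb_response(b, w, p) - w) * p
}

#' Train a Hebbian network on a set of epigenetic vectors
#'
#' Weights start at zero ("no prior association"); each epoch presents every
#' vector once, in shuffled order under `seed` when `shuffle = TRUE`, applying
#' [hebb_update()]. The final weight vector is the learned chromatin
#' signature: entry magnitudes near 1 mean the corresponding (mark, line)
#' presence or absence was consistent across regions. Entries that are 0 in a
#' denoised vector leave the corresponding weight untouched (the response
#' equals the weight there), so denoising zeros act as abstentions.
#'
#' @param x an `epivectors` object, matrix (rows = vectors) or list of
#'   equal-length vectors, entries in \{-1, 0, +1\}.
#' @param alpha learning/decay rate in (0, 1\] (default 0.1).
#' @param epochs passes over the data (default 1).
#' @param shuffle randomise presentation order each epoch (default `TRUE`).
#' @param seed RNG seed for shuffling.
#' @param mark_names,n_lines,flatten_order vector layout metadata; taken from
#'   `x` when it is an `epivectors` object. If absent, the whole vector is
#'   treated as a single pseudo-mark.
#' @return a `hebb_signature` object: list with `weights` (in \[-1, 1\]),
#'   `mark_names`, `n_lines`, `flatten_order` and training metadata.
#' @export
train_signature <- function(x, alpha = 0.1, epochs = 1L, shuffle = TRUE,
                            seed = 1L, mark_names = NULL, n_lines = NULL,
                            flatten_order = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1) stop("vectors have mixed lengths")
    x <- do.call(rbind, x)
  }
  stopifnot(is.matrix(x), alpha > 0, alpha <= 1, epochs >= 1)
  if (nrow(x) == 0) stop("cannot train on an empty vector set")
  if (!all(x %in% c(-1, 0, 1))) {
    stop("training vectors must have entries in {-1, 0, +1}")
  }
  mark_names <- mark_names %||% attr(x, "mark_names") %||% "signal"
  n_lines <- n_lines %||% attr(x, "n_lines") %||%
    (ncol(x) %/% length(mark_names))
  flatten_order <- flatten_order %||% attr(x, "flatten_order") %||% "column"
  stopifnot(ncol(x) == length(mark_names) * n_lines)

  n <- nrow(x)
  w <- numeric(ncol(x))
  run <- function() {
    for (ep in seq_len(epochs)) {
      idx <- if (shuffle) sample.int(n) else seq_len(n)
      for (i in idx) {
        w <<- hebb_update(w, x[i, ], alpha = alpha)
      }
    }
  }
  if (shuffle) withr::with_seed(seed, run()) else run()

  structure(list(weights = w,
                 mark_names = mark_names,
                 n_lines = as.integer(n_lines),
                 flatten_order = flatten_order,
                 alpha = alpha, epochs = as.integer(epochs),
                 shuffle = shuffle, seed = seed, n_regions = n),
            class = "hebb_signature")
}

#' Recall the learned signature from the trained network
#'
#' Presents the conditioned stimulus alone (all-zero epigenetic vector, ones
#' vector): the response is the prototype, i.e. the weight vector.
#'
#' @param signature a `hebb_signature`.
#' @return the recalled weight vector.
#' @export
recall <- function(signature) {
  stopifnot(inherits(signature, "hebb_signature"))
  w <- signature$weights
  hebb_response(rep(0, length(w)), w)
}

#' Signature weights as a marks-by-lines matrix
#'
#' @param signature a `hebb_signature`.
#' @return matrix with one row per mark (rownames = mark names), columns in
#'   genomic line order regardless of the flatten order used in training.
#' @export
signature_matrix <- function(signature) {
  stopifnot(inherits(signature, "hebb_signature"))
  m <- unflatten_vector(signature$weights,
                        n_marks = length(signature$mark_names),
                        n_lines = signature$n_lines,
                        order = signature$flatten_order)
  rownames(m) <- signature$mark_names
  m
}

#' @export
print.hebb_signature <- function(x, ...) {
  cat("Hebbian chromatin signature\n")
  cat(sprintf("  %d marks x %d lines (%s-wise flattening)\n",
              length(x$mark_names), x$n_lines, x$flatten_order))
  cat(sprintf("  trained on %d vectors; alpha = %g, epochs = %d, seed = %s\n",
              x$n_regions, x$alpha, x$epochs,
              if (x$shuffle) format(x$seed) else "(unshuffled)"))
  cat(sprintf("  weight range [%.3f, %.3f]\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Persist / reload a signature as TSV plus JSON metadata
#'
#' The weight matrix (marks x lines, row-labelled) goes to `path`; alpha,
#' epochs, seed, flatten order and region count go to `<path>.json`.
#'
#' @param signature a `hebb_signature`.
#' @param path output TSV path.
#' @return `path` invisibly (`write_signature`); the reloaded
#'   `hebb_signature` (`read_signature`).
#' @export
write_signature <- function(signature, path) {
  m <- signature_matrix(signature)
  df <- data.frame(mark = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("mark", paste0("line", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- signature[c("mark_names", "n_lines", "flatten_order", "alpha",
                      "epochs", "shuffle", "seed", "n_regions")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  dimnames(m) <- list(tab[[1]], NULL)
  structure(list(weights = flatten_matrix(m, meta$flatten_order),
                 mark_names = meta$mark_names,
                 n_lines = as.integer(meta$n_lines),
                 flatten_order = meta$flatten_order,
                 alpha = meta$alpha, epochs = as.integer(meta$epochs),
                 shuffle = meta$shuffle, seed = meta$seed,
                 n_regions = meta$n_regions),
            class = "hebb_signature")
}
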