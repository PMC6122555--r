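#' City-block (Manhattan) distance between two vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sum(abs(x - y))`.
#' @export
cityblock <- function(x, y) {
  if (length(x) != length(y)) {
    stop("cityblock: vectors must have equal lengths")
  }
  sum(abs(x - y))
}

#' WPGMA hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative bottom-up clustering under the weighted pair group method
#' with arithmetic mean: at each step the two closest active clusters merge,
#' and the distance from the merged cluster (A, B) to any other C becomes
#' `(d(A, C) + d(B, C)) / 2`, regardless of cluster sizes. Ties are broken by
#' the lexicographically smallest pair of cluster indices and the leaf order
#' reads each merge lower-index subtree first, so the result -- and any image
#' rendered from it -- is fully reproducible.
#'
#' @param x a numeric matrix whose rows are the items to cluster (distances
#'   are pairwise [cityblock()]), or a `dist` object holding precomputed
#'   distances.
#' @param labels optional item labels; defaults to rownames or `item<i>`.
#' @return a `mark_dendrogram`: list with `merges` (data.frame of cluster ids
#'   `a`, `b` and merge `height`; leaves are ids `1..k`, merge step `s`
#'   creates id `k + s`), `labels`, `leaf_order` and `n_leaves`.
#' @export
wpgma <- function(x, labels = NULL) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    k <- nrow(x)
    D <- matrix(0, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i < j) D[i, j] <- D[j, i] <- cityblock(x[i, ], x[j, ])
      }
    }
    labels <- labels %||% rownames(x)
  }
  k <- nrow(D)
  labels <- labels %||% paste0("item", seq_len(k))
  stopifnot(length(labels) == k)

  children <- vector("list", 2L * k - 1L)
  if (k == 1) {
    return(structure(list(merges = data.frame(a = integer(), b = integer(),
                                              height = numeric()),
                          labels = labels, leaf_order = 1L, n_leaves = 1L,
                          children = children),
                     class = "mark_dendrogram"))
  }

  M <- matrix(NA_real_, 2L * k - 1L, 2L * k - 1L)
  M[seq_len(k), seq_len(k)] <- D
  active <- seq_len(k)
  merges <- data.frame(a = integer(k - 1L), b = integer(k - 1L),
                       height = numeric(k - 1L))
  for (step in seq_len(k - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (ii < jj) {
          d <- M[active[ii], active[jj]]
          if (d < best_d) {  # strict: first (lexicographically smallest) wins
            best_d <- d
            best <- c(active[ii], active[jj])
          }
        }
      }
    }
    new_id <- k + step
    children[[new_id]] <- best
    merges$a[step] <- best[1]
    merges$b[step] <- best[2]
    merges$height[step] <- best_d
    rest <- setdiff(active, best)
    for (cc in rest) {
      M[new_id, cc] <- M[cc, new_id] <- (M[best[1], cc] + M[best[2], cc]) / 2
    }
    active <- sort(c(rest, new_id))
  }
  if (is.unsorted(merges$height)) {
    warning("non-monotone merge heights (inversion in the linkage)")
  }

  leaves_of <- function(id) {
    if (id <= k) id else c(leaves_of(children[[id]][1]),
                           leaves_of(children[[id]][2]))
  }
  structure(list(merges = merges, labels = labels,
                 leaf_order = leaves_of(2L * k - 1L), n_leaves = k,
                 children = children),
            class = "mark_dendrogram")
}

#' @export
print.mark_dendrogram <- function(x, ...) {
  cat(sprintf("WPGMA dendrogram over %d items\n", x$n_leaves))
  cat("leaf order:", paste(x$labels[x$leaf_order], collapse = ", "), "\n")
  if (nrow(x$merges)) {
    cat(sprintf("merge heights: %s\n",
                paste(signif(x$merges$height, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Convert a mark_dendrogram to a base-R hclust object
#'
#' @param x a `mark_dendrogram` with at least 2 leaves.
#' @param ... unused.
#' @return an `hclust` object (usable with `plot()`, `ape::as.phylo()`, ...).
#' @export
as.hclust.mark_dendrogram <- function(x, ...) {
  k <- x$n_leaves
  if (k < 2) stop("cannot convert a single-leaf dendrogram to hclust")
  remap <- function(id) if (id <= k) -id else id - k
  structure(list(merge = cbind(vapply(x$merges$a, remap, numeric(1)),
                               vapply(x$merges$b, remap, numeric(1))),
                 height = x$merges$height,
                 order = x$leaf_order,
                 labels = x$labels,
                 method = "wpgma",
                 dist.method = "cityblock",
                 call = match.call()),
            class = "hclust")
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become node heights (ultrametric branch lengths) via the
#' `hclust` -> `ape::as.phylo` route.
#'
#' @param dend a `mark_dendrogram`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(as.hclust(dend))
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Render a signature as a digitised red/blue image
#'
#' Each weight paints a `cell_px` x `cell_px` block: +1 is pure red
#' (255, 0, 0), -1 pure blue (0, 0, 255), with linear interpolation in
#' between (`red = round(255 * (v + 1) / 2)`, ties away from zero;
#' `blue = 255 - red`; green stays 0). Values outside \[-1, 1\] are clipped.
#' Mark rows are ordered by the WPGMA dendrogram so marks with similar
#' distributions sit together.
#'
#' @param signature a `hebb_signature`.
#' @param dendrogram optional `mark_dendrogram` over the signature's marks;
#'   computed from the weight rows when omitted.
#' @param cell_px pixels per matrix cell (default 10).
#' @return a `signature_image`: list with `pixels` (an
#'   `(marks*cell_px) x (lines*cell_px) x 3` integer array, 0-255),
#'   `row_labels` (marks in leaf order), `cell_px`, `dendrogram`.
#' @export
render_signature <- function(signature, dendrogram = NULL, cell_px = 10L) {
  stopifnot(inherits(signature, "hebb_signature"), cell_px >= 1)
  W <- signature_matrix(signature)
  m <- nrow(W)
  if (is.null(dendrogram)) {
    dendrogram <- if (m >= 2) wpgma(W) else wpgma(W, labels = rownames(W))
  }
  if (dendrogram$n_leaves != m ||
      !setequal(dendrogram$labels, rownames(W))) {
    stop("dendrogram leaves do not match the signature's marks")
  }
  ord <- match(dendrogram$labels[dendrogram$leaf_order], rownames(W))
  v <- pmin(pmax(W[ord, , drop = FALSE], -1), 1)
  red <- round_half_away(255 * (v + 1) / 2)
  ri <- rep(seq_len(m), each = cell_px)
  ci <- rep(seq_len(ncol(W)), each = cell_px)
  pix <- array(0L, dim = c(m * cell_px, ncol(W) * cell_px, 3L))
  pix[, , 1] <- red[ri, ci]
  pix[, , 3] <- 255L - red[ri, ci]
  structure(list(pixels = pix,
                 row_labels = rownames(W)[ord],
                 cell_px = as.integer(cell_px),
                 dendrogram = dendrogram),
            class = "signature_image")
}

#' Write a rendered signature image to a PNG file
#'
#' Output is bit-exact under fixed inputs (no text, anti-aliasing or device
#' state is involved); use [plot.hebb_signature()] for a labelled interactive
#' view.
#'
#' @param x a `signature_image` or a `hebb_signature` (rendered with
#'   defaults).
#' @param path output PNG path.
#' @param ... passed on to [render_signature()] when `x` is a signature.
#' @return `path`, invisibly.
#' @export
write_signature_png <- function(x, path, ...) {
  if (inherits(x, "hebb_signature")) {
    x <- render_signature(x, ...)
  }
  stopifnot(inherits(x, "signature_image"))
  png::writePNG(x$pixels / 255, target = path)
  invisible(path)
}

#' Plot a signature as a labelled heat image
#'
#' Convenience device plot: same red/blue mapping as [render_signature()],
#' mark labels on the left in dendrogram leaf order (top to bottom).
#'
#' @param x a `hebb_signature`.
#' @param dendrogram optional `mark_dendrogram`; computed when omitted.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the leaf-ordered weight matrix.
#' @export
plot.hebb_signature <- function(x, dendrogram = NULL, ...) {
  img <- render_signature(x, dendrogram = dendrogram, cell_px = 1L)
  W <- signature_matrix(x)[img$row_labels, , drop = FALSE]
  pal <- grDevices::rgb(seq(0, 1, length.out = 256), 0,
                        seq(1, 0, length.out = 256))
  op <- graphics::par(mar = c(2, 8, 1, 1))
  on.exit(graphics::par(op))
  graphics::image(t(W[rev(seq_len(nrow(W))), , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE, ...)
  graphics::axis(2, at = seq(1, 0, length.out = nrow(W)),
                 labels = img$row_labels, las = 2, tick = FALSE,
                 cex.axis = 0.8)
  invisible(W)
}

#' Componentwise mean of a set of epigenetic vectors
#'
#' The average-profile baseline: no learning, just the arithmetic mean of
#' every entry across regions. Values lie in \[-1, 1\] and show a fuzzier
#' version of the pattern the network sharpens.
#'
#' @param x matrix (rows = vectors) or `epivectors`.
#' @return numeric vector of column means.
#' @export
average_profile <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) == 0) stop("cannot average an empty vector set")
  colMeans(x)
}

#' Cluster whole region vectors
#'
#' The same city-block + WPGMA machinery as [wpgma()], applied to region
#' epigenetic vectors (conventionally row-wise flattened, so each mark's
#' full row stays contiguous) instead of mark rows.
#'
#' @param x matrix of region vectors (rows = regions) or `epivectors`.
#' @param labels optional region labels.
#' @return a `mark_dendrogram` over the regions.
#' @export
cluster_regions <- function(x, labels = NULL) {
  stopifnot(is.matrix(x))
  labels <- labels %||% rownames(x) %||% paste0("region", seq_len(nrow(x)))
  wpgma(unclass(x), labels = labels)
}
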