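#' Coordinates of the equally spaced vertical lines across a region
#'
#' A region `[s, e)` (0-based half-open) carries `n_lines` vertical sampling
#' lines at `s + k * (e - s) / (n_lines - 1)` for `k = 0 .. n_lines - 1`:
#' the first line sits on the region start, the last on the region end.
#' Positions are real-valued; no rounding is applied, so membership tests
#' against integer peak boundaries are exact.
#'
#' @param region a length-1 `GRanges`.
#' @param n_lines number of lines (>= 2). Think of it as the resolution:
#'   41 suits ~400 bp elements, 91 longer ones.
#' @return numeric vector of `n_lines` 0-based coordinates.
#' @export
line_positions <- function(region, n_lines = 41L) {
  stopifnot(length(region) == 1, n_lines >= 2)
  s0 <- start(region) - 1
  e0 <- end(region)
  if (e0 <= s0) {
    stop("degenerate region (zero width): cannot place vertical lines")
  }
  s0 + (0:(n_lines - 1)) * (e0 - s0) / (n_lines - 1)
}

# disjoint sorted 0-based half-open intervals of one track on one chromosome
.track_chrom_intervals <- function(track, chrom) {
  sub <- track[as.character(seqnames(track)) == chrom]
  r <- reduce(sub, ignore.strand = TRUE)
  list(s0 = start(r) - 1, e0 = end(r))
}

# membership of real positions in a disjoint sorted half-open interval set
.covered <- function(pos, iv) {
  if (length(iv$s0) == 0) {
    return(rep(FALSE, length(pos)))
  }
  fi <- findInterval(pos, iv$s0)
  hit <- fi > 0
  hit[hit] <- pos[hit] < iv$e0[fi[hit]]
  hit
}

#' Encode one region against a stack of mark tracks
#'
#' Builds the marks-by-lines matrix of a region: entry (i, j) is +1 when some
#' peak interval of track i contains the j-th vertical line position (half-open
#' membership, `start <= p < end` in 0-based coordinates), else -1. A track
#' with no intervals on the region's chromosome yields an all -1 row. With
#' `orient_by_strand = TRUE`, minus-strand regions have their columns reversed
#' so that column 1 is always the 5' end of the annotated element.
#'
#' @param region a length-1 `GRanges`.
#' @param tracks named list of `GRanges` peak tracks, one per histone mark.
#' @param n_lines number of vertical lines (default 41).
#' @param orient_by_strand reverse columns for minus-strand regions
#'   (default `FALSE`).
#' @return a numeric matrix in \{-1, +1\} with one row per mark (rownames =
#'   mark names) and `n_lines` columns.
#' @examples
#' region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 210))
#' trk <- list(m1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(116, 155)))
#' encode_region(region, trk, n_lines = 5)
#' @export
encode_region <- function(region, tracks, n_lines = 41L,
                          orient_by_strand = FALSE) {
  tracks <- .as_track_list(tracks)
  pos <- line_positions(region, n_lines)
  chrom <- as.character(seqnames(region))
  mat <- t(vapply(tracks, function(trk) {
    ifelse(.covered(pos, .track_chrom_intervals(trk, chrom)), 1, -1)
  }, numeric(length(pos))))
  rownames(mat) <- names(tracks)
  if (orient_by_strand && as.character(strand(region)) == "-") {
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  }
  mat
}

.as_track_list <- function(tracks) {
  if (inherits(tracks, "GRanges")) {
    tracks <- list(mark = tracks)
  }
  if (!is.list(tracks) || length(tracks) == 0) {
    stop("'tracks' must be a non-empty named list of GRanges, one per mark")
  }
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("every mark track must be named")
  }
  tracks
}

#' Flatten a marks-by-lines matrix into an epigenetic vector
#'
#' Column-wise flattening (the default used for network training) interleaves
#' marks within each line: entry (i, j) lands at index `(j - 1) * m + i` for
#' `m` marks. Row-wise flattening concatenates whole mark rows
#' (index `(i - 1) * n + j`) and is the layout used when clustering region
#' vectors. Both are lossless; [unflatten_vector()] inverts them.
#'
#' @param mat a marks-by-lines matrix.
#' @param order `"column"` (default) or `"row"`.
#' @return a numeric vector of length `nrow(mat) * ncol(mat)`.
#' @export
flatten_matrix <- function(mat, order = c("column", "row")) {
  order <- match.arg(order)
  if (order == "column") as.vector(mat) else as.vector(t(mat))
}

#' Recover the marks-by-lines matrix from an epigenetic vector
#'
#' @param values flattened vector of length `n_marks * n_lines`.
#' @param n_marks number of mark rows.
#' @param n_lines number of line columns.
#' @param order flatten order used, `"column"` or `"row"`.
#' @return a `n_marks` x `n_lines` matrix.
#' @export
unflatten_vector <- function(values, n_marks, n_lines,
                             order = c("column", "row")) {
  order <- match.arg(order)
  stopifnot(length(values) == n_marks * n_lines)
  matrix(values, nrow = n_marks, ncol = n_lines, byrow = (order == "row"))
}

#' Encode a whole region set into epigenetic vectors
#'
#' Applies [encode_region()] to every region (vectorised internally over the
#' line positions of all regions at once) and flattens each matrix, yielding
#' one epigenetic vector per region. The result carries the mark names, line
#' count and flatten order needed by the downstream preprocessing, training
#' and analysis steps.
#'
#' @param regions a `GRanges` of regions of interest.
#' @param tracks named list of `GRanges` peak tracks.
#' @param n_lines number of vertical lines per region (default 41).
#' @param flatten_order `"column"` (default) or `"row"`.
#' @param orient_by_strand reverse columns of minus-strand regions
#'   (default `FALSE`).
#' @return an `epivectors` object: a regions x (marks * lines) matrix in
#'   \{-1, +1\} with attributes `mark_names`, `n_lines`, `flatten_order`.
#' @export
encode_regions <- function(regions, tracks, n_lines = 41L,
                           flatten_order = c("column", "row"),
                           orient_by_strand = FALSE) {
  flatten_order <- match.arg(flatten_order)
  tracks <- .as_track_list(tracks)
  stopifnot(length(regions) > 0, n_lines >= 2)
  if (any(width(regions) < 1)) {
    stop("degenerate (zero-width) region in input")
  }

  n_reg <- length(regions)
  m <- length(tracks)
  s0 <- start(regions) - 1
  e0 <- end(regions)
  chrom <- as.character(seqnames(regions))
  # P[r, k]: position of line k in region r
  P <- s0 + outer(e0 - s0, 0:(n_lines - 1)) / (n_lines - 1)

  flip <- orient_by_strand & as.character(strand(regions)) == "-"
  out <- matrix(-1, nrow = n_reg, ncol = m * n_lines)
  for (j in seq_len(m)) {
    hits <- matrix(FALSE, n_reg, n_lines)
    for (cc in unique(chrom)) {
      rows <- which(chrom == cc)
      iv <- .track_chrom_intervals(tracks[[j]], cc)
      hits[rows, ] <- .covered(P[rows, , drop = FALSE], iv)
    }
    if (any(flip)) {
      hits[flip, ] <- hits[flip, rev(seq_len(n_lines)), drop = FALSE]
    }
    cols <- if (flatten_order == "column") {
      (seq_len(n_lines) - 1L) * m + j
    } else {
      (j - 1L) * n_lines + seq_len(n_lines)
    }
    out[, cols] <- ifelse(hits, 1, -1)
  }
  epivectors(out, mark_names = names(tracks), n_lines = n_lines,
             flatten_order = flatten_order)
}

#' Construct an epigenetic-vector matrix with its metadata
#'
#' @param values regions x (marks * lines) numeric matrix with entries in
#'   \{-1, 0, +1\}.
#' @param mark_names ordered mark labels.
#' @param n_lines lines per mark.
#' @param flatten_order `"column"` or `"row"`.
#' @return an `epivectors` object (a classed matrix).
#' @export
epivectors <- function(values, mark_names, n_lines,
                       flatten_order = c("column", "row")) {
  flatten_order <- match.arg(flatten_order)
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(mark_names) * n_lines)
  structure(values,
            mark_names = as.character(mark_names),
            n_lines = as.integer(n_lines),
            flatten_order = flatten_order,
            class = c("epivectors", class(matrix())))
}

# rebuild metadata after a row-subsetting or transforming operation
.restamp <- function(values, template) {
  epivectors(values,
             mark_names = attr(template, "mark_names"),
             n_lines = attr(template, "n_lines"),
             flatten_order = attr(template, "flatten_order"))
}

#' Persist epigenetic vectors as TSV plus a JSON sidecar
#'
#' The matrix is written as a plain tab-separated table (rows = regions, no
#' header) and the mark names, line count and flatten order go to
#' `<path>.json`, so a later session (or the command-line interface) can
#' reload the set losslessly with [read_epivectors()].
#'
#' @param x an `epivectors` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_epivectors <- function(x, path) {
  stopifnot(inherits(x, "epivectors"))
  write.table(unclass(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(mark_names = attr(x, "mark_names"),
               n_lines = attr(x, "n_lines"),
               flatten_order = attr(x, "flatten_order"),
               n_vectors = nrow(x))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epivectors
#' @export
read_epivectors <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  epivectors(values, mark_names = meta$mark_names, n_lines = meta$n_lines,
             flatten_order = meta$flatten_order)
}
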