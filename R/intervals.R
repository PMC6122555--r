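#' Read a BED file into a GRanges
#'
#' Reads BED3+ (tab-separated) interval data -- a region set or a histone-mark
#' peak track -- into a `GRanges`. BED coordinates are 0-based half-open; the
#' returned `GRanges` follows the usual 1-based closed convention, so an input
#' line `chr1 100 200` becomes `chr1:101-200`. Strand is taken from column 6
#' when present (`+`/`-`), otherwise `*`. `#`-comment, `track` and `browser`
#' lines are skipped. Malformed lines (too few fields, non-integer or negative
#' coordinates, start >= end) raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param min_columns minimum number of tab-separated fields each data line
#'   must have (at least 3).
#' @return a `GRanges` with metadata columns `name` and `score` when present.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr2\t10\t50\tx\t0\t-"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, min_columns = 3L) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path)
  }
  min_columns <- max(3L, as.integer(min_columns))
  raw <- readLines(path)
  keep <- nzchar(trimws(raw)) &
    !grepl("^(#|track\\b|browser\\b)", raw)
  if (!any(keep)) {
    stop("no interval lines in BED file: ", path)
  }
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)

  fail <- function(i, why) {
    stop(sprintf("%s at line %d of %s", why, lineno[i], path), call. = FALSE)
  }
  bad <- which(nf < min_columns)
  if (length(bad)) {
    fail(bad[1], sprintf("expected >= %d tab-separated fields, got %d",
                         min_columns, nf[bad[1]]))
  }

  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad)) fail(bad[1], "non-integer coordinate")
  bad <- which(s < 0)
  if (length(bad)) fail(bad[1], "negative start coordinate")
  bad <- which(s >= e)
  if (length(bad)) fail(bad[1], "start >= end")

  std <- rep("*", length(chrom))
  has6 <- nf >= 6L
  if (any(has6)) {
    raw_std <- vapply(fields[has6], `[[`, character(1), 6L)
    std[has6] <- ifelse(raw_std %in% c("+", "-"), raw_std, "*")
  }
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e), strand = std)
  if (any(nf >= 4L)) {
    nm <- rep(".", length(chrom))
    nm[nf >= 4L] <- vapply(fields[nf >= 4L], `[[`, character(1), 4L)
    mcols(gr)$name <- nm
  }
  if (any(nf >= 5L)) {
    sc <- rep(0, length(chrom))
    sc[nf >= 5L] <- suppressWarnings(
      as.numeric(vapply(fields[nf >= 5L], `[[`, character(1), 5L)))
    sc[is.na(sc)] <- 0
    mcols(gr)$score <- sc
  }
  gr
}

#' Write a GRanges to a BED6 file
#'
#' The inverse of [read_bed()]: 1-based closed `GRanges` coordinates are
#' written back as 0-based half-open BED. Missing names become `.`, missing
#' scores 0, and `*` strand is written as `.`.
#'
#' @param x a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  nm <- mcols(x)$name %||% rep(".", length(x))
  sc <- mcols(x)$score %||% rep(0, length(x))
  std <- as.character(strand(x))
  std[std == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L,
                   end = end(x),
                   name = nm, score = sc, strand = std)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Expand regions by a fraction of their length on each end
#'
#' Each interval of length L grows by `round(fraction * L)` base pairs on both
#' sides (ties rounded away from zero), truncated at the chromosome start.
#' This is the curation step used to look just outside a genetic element, so
#' the learned signature shows how marks differ from the surroundings. No
#' right-truncation is applied (no chromosome-sizes file is consulted).
#'
#' @param x a `GRanges`.
#' @param fraction non-negative expansion proportion (default 0.1, i.e. 10%
#'   of the region length added on each end).
#' @return the expanded `GRanges`; strand and metadata are preserved.
#' @export
expand_regions <- function(x, fraction = 0.1) {
  stopifnot(is.numeric(fraction), length(fraction) == 1, fraction >= 0)
  pad <- round_half_away(fraction * width(x))
  out <- GRanges(seqnames(x),
                 IRanges(start = pmax(1, start(x) - pad), end = end(x) + pad),
                 strand = strand(x))
  mcols(out) <- mcols(x)
  out
}

#' Merge overlapping (and abutting) regions
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases, per chromosome. Merging ignores strand; when every input interval
#' carries the same explicit strand (the usual case after strand-based
#' partitioning) that strand is restored on the output.
#'
#' @param x a `GRanges`.
#' @param ignore_strand merge across strands (default). Set `FALSE` for
#'   mixed-strand sets feeding a strand-oriented encoding, where each strand
#'   group must keep its annotation and is merged separately.
#' @return a sorted, disjoint `GRanges` (metadata columns are dropped).
#' @export
merge_overlaps <- function(x, ignore_strand = TRUE) {
  out <- reduce(x, ignore.strand = ignore_strand)
  if (ignore_strand) {
    st <- unique(as.character(strand(x)))
    if (length(st) == 1 && st != "*") {
      strand(out) <- st
    }
  }
  sort(out, ignore.strand = TRUE)
}

#' Down-sample a large region set uniformly per chromosome
#'
#' If the set holds more than `threshold` regions, draw `per_chrom` regions
#' (or all available, if fewer) uniformly without replacement from each
#' chromosome under the given seed; smaller sets pass through unchanged.
#' Output is coordinate-sorted. The defaults mirror the usual curation rule:
#' sets above 10,000 regions are cut to 500 per chromosome.
#'
#' @param x a `GRanges`.
#' @param per_chrom regions to keep per chromosome when sampling (default 500).
#' @param threshold set size above which sampling kicks in (default 10000).
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @return a `GRanges` subset of `x` (or `x` itself when below threshold).
#' @export
sample_regions <- function(x, per_chrom = 500L, threshold = 10000L, seed = 1L) {
  stopifnot(per_chrom > 0, threshold > 0)
  if (length(x) <= threshold) {
    return(x)
  }
  chrom <- as.character(seqnames(x))
  idx <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(chrom)), function(cc) {
      w <- which(chrom == cc)
      if (length(w) <= per_chrom) w else w[sample.int(length(w), per_chrom)]
    }), use.names = FALSE)
  })
  sort(x[idx], ignore.strand = TRUE)
}
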