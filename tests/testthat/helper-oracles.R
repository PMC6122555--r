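# shared fixtures and independent oracles for the test suite

library(GenomicRanges)

gr <- function(chrom, s0, e0, strand = "*") {
  GRanges(chrom, IRanges(s0 + 1, e0), strand = strand)
}

write_bed_lines <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# brute-force encoding oracle: test every (interval, line) pair directly.
# tracks: list of data.frames with s0/e0 columns (0-based half-open).
brute_encode <- function(s0, e0, tracks, n_lines) {
  pos <- s0 + (0:(n_lines - 1)) * (e0 - s0) / (n_lines - 1)
  t(vapply(tracks, function(trk) {
    vapply(pos, function(p) {
      hit <- FALSE
      for (r in seq_len(nrow(trk))) {
        if (trk$s0[r] <= p && p < trk$e0[r]) hit <- TRUE
      }
      if (hit) 1 else -1
    }, numeric(1))
  }, numeric(n_lines)))
}

# per-base union oracle for merge_overlaps (coordinates < 1000)
covered_bases <- function(g) {
  out <- character(0)
  for (i in seq_along(g)) {
    cc <- as.character(seqnames(g)[i])
    out <- c(out, paste(cc, seq(start(g)[i], end(g)[i])))
  }
  unique(out)
}

# independent WPGMA oracle: clusters as nested trees; the distance between
# two trees is recomputed from scratch by the defining weighted recursion,
# never by incremental matrix updates.
wpgma_oracle <- function(D) {
  k <- nrow(D)
  tree_dist <- function(t1, t2) {
    if (length(t1) == 1 && length(t2) == 1) {
      return(D[t1[[1]], t2[[1]]])
    }
    if (length(t1) == 2) {
      return((tree_dist(t1[[1]], t2) + tree_dist(t1[[2]], t2)) / 2)
    }
    (tree_dist(t1, t2[[1]]) + tree_dist(t1, t2[[2]])) / 2
  }
  # active clusters keyed by the same id scheme as wpgma(): leaves 1..k,
  # merge s creates id k + s; tie-break = lexicographically smallest id pair
  trees <- lapply(seq_len(k), function(i) list(i))
  ids <- seq_len(k)
  heights <- numeric(k - 1)
  pairs <- matrix(0L, k - 1, 2)
  for (step in seq_len(k - 1)) {
    best_d <- Inf
    best <- c(NA, NA)
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a < b) {
          d <- tree_dist(trees[[a]], trees[[b]])
          if (d < best_d) {
            best_d <- d
            best <- c(a, b)
          }
        }
      }
    }
    heights[step] <- best_d
    pairs[step, ] <- c(ids[best[1]], ids[best[2]])
    merged <- list(trees[[best[1]]], trees[[best[2]]])
    trees <- c(trees[-best], list(merged))
    ids <- c(ids[-best], k + step)
    ord <- order(ids)
    trees <- trees[ord]
    ids <- ids[ord]
  }
  list(heights = heights, pairs = pairs)
}

# full simulate -> curate -> encode -> preprocess -> train pipeline used by
# several recovery tests
run_pipeline <- function(planted, seed, dir = tempfile(),
                         orient_by_strand = FALSE, strand_subset = NULL) {
  paths <- simulate_tracks(planted, dir)
  regions <- read_bed(paths$regions)
  regions <- expand_regions(regions, planted$expansion_fraction)
  regions <- merge_overlaps(regions, ignore_strand = !orient_by_strand &&
                              is.null(strand_subset))
  if (!is.null(strand_subset)) {
    regions <- regions[as.character(strand(regions)) == strand_subset]
  }
  tracks <- lapply(paths$marks, read_bed)
  ev <- encode_regions(regions, tracks, n_lines = planted$n_lines,
                       orient_by_strand = orient_by_strand)
  ev <- filter_background(ev)
  ev <- denoise_vectors(ev, seed = seed)
  train_signature(ev, seed = seed)
}
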