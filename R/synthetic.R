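#' Describe a planted chromatin signature for fixture generation
#'
#' Defines the ground truth for synthetic data: a hard +/-1 positional
#' profile per mark over `n_lines` vertical lines, an independent flip-noise
#' rate corrupting each (region, mark, line) presence bit, and the region
#' geometry. The profile is laid out on the *expanded* region (the expansion
#' fraction is part of the config), so the standard curation pipeline --
#' read, expand, merge, encode -- inverts generation exactly at zero noise.
#'
#' The expanded-region line spacing `(L + 2 * round(f * L)) / (n_lines - 1)`
#' must be an even positive integer so every planted peak boundary is an
#' integer BED coordinate; the defaults (400 bp regions, 10% expansion, 41
#' lines) give a spacing of 12 bp. The default per-mark profile is a single
#' contiguous run of +1 (a peaked mark) with random position and width,
#' drawn under `seed`.
#'
#' @param n_marks number of histone marks (default 10).
#' @param n_lines vertical lines per region (default 41).
#' @param region_length core region length in bp (default 400).
#' @param n_regions number of regions (default 500).
#' @param flip_noise per-bit flip probability in \[0, 0.5) (default 0.1).
#' @param expansion_fraction curation expansion used downstream (default 0.1).
#' @param pattern optional `n_marks` x `n_lines` matrix in \{-1, +1\};
#'   generated when omitted.
#' @param mark_names mark labels.
#' @param chrom synthetic chromosome name (default `"chrS1"`).
#' @param strands per-region strand vector (default all `"+"`).
#' @param seed integer seed controlling the profile draw and (offset by one)
#'   the flip noise in [simulate_tracks()].
#' @return a `planted_signature` object.
#' @export
planted_signature <- function(n_marks = 10L, n_lines = 41L,
                              region_length = 400L, n_regions = 500L,
                              flip_noise = 0.1, expansion_fraction = 0.1,
                              pattern = NULL,
                              mark_names = sprintf("mark%02d", seq_len(n_marks)),
                              chrom = "chrS1", strands = NULL, seed = 1L) {
  stopifnot(flip_noise >= 0, flip_noise < 0.5, n_lines >= 2, n_regions >= 1,
            region_length >= n_lines)
  pad <- round_half_away(expansion_fraction * region_length)
  exp_len <- region_length + 2 * pad
  spacing <- exp_len / (n_lines - 1)
  if (spacing != floor(spacing) || spacing %% 2 != 0 || spacing < 2) {
    stop("expanded region length (", exp_len, " bp) over ", n_lines - 1,
         " line gaps gives spacing ", format(spacing),
         "; it must be an even integer >= 2 so peak boundaries are exact ",
         "BED coordinates")
  }
  if (is.null(pattern)) {
    pattern <- withr::with_seed(seed, {
      t(vapply(seq_len(n_marks), function(j) {
        w <- sample(5:max(5L, n_lines %/% 2L), 1)
        st <- sample.int(n_lines - w + 1L, 1)
        row <- rep(-1, n_lines)
        row[st:(st + w - 1L)] <- 1
        row
      }, numeric(n_lines)))
    })
  }
  pattern <- as.matrix(pattern)
  stopifnot(nrow(pattern) == n_marks, ncol(pattern) == n_lines,
            all(pattern %in% c(-1, 1)))
  rownames(pattern) <- mark_names
  strands <- strands %||% rep("+", n_regions)
  stopifnot(length(strands) == n_regions, all(strands %in% c("+", "-")))
  structure(list(pattern = pattern, mark_names = mark_names,
                 n_marks = as.integer(n_marks), n_lines = as.integer(n_lines),
                 region_length = as.integer(region_length),
                 n_regions = as.integer(n_regions),
                 flip_noise = flip_noise,
                 expansion_fraction = expansion_fraction,
                 pad = as.integer(pad), spacing = as.integer(spacing),
                 chrom = chrom, strands = strands, seed = as.integer(seed)),
            class = "planted_signature")
}

#' @export
print.planted_signature <- function(x, ...) {
  cat(sprintf(paste0("planted signature: %d marks x %d lines, %d regions of ",
                     "%d bp (+%d bp pad), flip noise %g, seed %d\n"),
              x$n_marks, x$n_lines, x$n_regions, x$region_length, x$pad,
              x$flip_noise, x$seed))
  invisible(x)
}

#' Turn a fixture into a strand-mirrored one
#'
#' Alternates region strands between `+` and `-`; minus-strand regions will
#' be generated from the column-reversed profile, emulating elements
#' annotated on either strand whose chromatin layout follows the element's
#' own 5'-to-3' direction. Training the two strand groups separately should
#' then yield mirror-image signatures; training jointly with strand
#' orientation should recover the plus-strand profile. Warns when every
#' profile row is palindromic (the mirror test would be vacuous).
#'
#' @param planted a `planted_signature`.
#' @return the modified `planted_signature`.
#' @export
mirror_fixture <- function(planted) {
  stopifnot(inherits(planted, "planted_signature"))
  rev_pat <- planted$pattern[, rev(seq_len(planted$n_lines)), drop = FALSE]
  if (all(rev_pat == planted$pattern)) {
    warning("planted profile is symmetric; mirror test would be vacuous")
  }
  planted$strands <- rep(c("+", "-"), length.out = planted$n_regions)
  planted
}

#' Generate BED fixtures from a planted signature
#'
#' Places `n_regions` non-overlapping core regions on a synthetic chromosome
#' (spaced three expanded lengths apart, so expansion plus merging is a
#' no-op), then for every (region, mark) draws line-level presence bits from
#' the planted profile (column-reversed for minus-strand regions), flips each
#' independently with probability `flip_noise`, and converts present lines to
#' peak intervals covering a window of one line spacing centred on the line;
#' runs of adjacent present lines are written as one merged interval. Outputs
#' are a BED6 region file, one BED3 peak file per mark, and a JSON truth file
#' holding the planted pattern and full config. Identical seeds give
#' byte-identical files.
#'
#' @param planted a `planted_signature`.
#' @param out_dir output directory (created if needed).
#' @return list with `regions` (path), `marks` (named vector of per-mark BED
#'   paths) and `truth` (JSON path).
#' @export
simulate_tracks <- function(planted, out_dir) {
  stopifnot(inherits(planted, "planted_signature"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory is not writable: ", out_dir)
  }
  p <- planted
  exp_len <- p$region_length + 2L * p$pad
  half <- p$spacing %/% 2L
  core_s0 <- exp_len + (seq_len(p$n_regions) - 1L) * 3L * exp_len
  exp_s0 <- core_s0 - p$pad

  # presence bits: flips drawn mark-major then region-major, fixed order
  mark_beds <- withr::with_seed(p$seed + 1L, {
    lapply(seq_len(p$n_marks), function(j) {
      rows <- lapply(seq_len(p$n_regions), function(i) {
        prof <- p$pattern[j, ]
        if (p$strands[i] == "-") prof <- rev(prof)
        present <- xor(prof == 1, runif(p$n_lines) < p$flip_noise)
        if (!any(present)) {
          return(NULL)
        }
        runs <- rle(present)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        on <- which(runs$values)
        pos0 <- exp_s0[i] + (starts[on] - 1L) * p$spacing
        pos1 <- exp_s0[i] + (ends[on] - 1L) * p$spacing
        cbind(pos0 - half, pos1 + half)
      })
      do.call(rbind, rows)
    })
  })

  region_path <- file.path(out_dir, "regions.bed")
  region_df <- data.frame(chrom = p$chrom, start = core_s0,
                          end = core_s0 + p$region_length,
                          name = sprintf("region%05d", seq_len(p$n_regions)),
                          score = 0L, strand = p$strands)
  write.table(region_df, region_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  mark_paths <- vapply(seq_len(p$n_marks), function(j) {
    path <- file.path(out_dir, paste0(p$mark_names[j], ".bed"))
    iv <- mark_beds[[j]]
    if (is.null(iv)) {
      # a fully absent mark can only happen at extreme noise; keep the file
      # valid for the reader by emitting nothing and warning
      warning("mark ", p$mark_names[j], " has no intervals")
      file.create(path)
    } else {
      write.table(data.frame(p$chrom, iv[, 1], iv[, 2]), path, sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    path
  }, character(1))
  names(mark_paths) <- p$mark_names

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(pattern = unname(p$pattern), mark_names = p$mark_names,
         n_lines = p$n_lines, region_length = p$region_length,
         n_regions = p$n_regions, flip_noise = p$flip_noise,
         expansion_fraction = p$expansion_fraction, chrom = p$chrom,
         strands = p$strands, seed = p$seed),
    truth_path, auto_unbox = TRUE, digits = NA)

  list(regions = region_path, marks = mark_paths, truth = truth_path)
}

#' Reload the planted truth written by simulate_tracks
#'
#' @param path path to a `truth.json` file.
#' @return the corresponding `planted_signature`.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted_signature(n_marks = length(tr$mark_names), n_lines = tr$n_lines,
                    region_length = tr$region_length,
                    n_regions = tr$n_regions, flip_noise = tr$flip_noise,
                    expansion_fraction = tr$expansion_fraction,
                    pattern = tr$pattern, mark_names = tr$mark_names,
                    chrom = tr$chrom, strands = tr$strands, seed = tr$seed)
}
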