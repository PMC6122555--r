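#' Normalised dot product (cosine similarity) of two vectors
#'
#' `dotsim(x, y) = (x / ||x||) . (y / ||y||)`, in \[-1, +1\]: 1 for vectors
#' pointing the same way, -1 for entrywise-opposite ones, near 0 when the
#' distributions are unrelated. If either vector has zero norm the similarity
#' is undefined; by convention 0 is returned (downstream classification then
#' flags the comparison as inconsistent), since zero rows are expected from
#' denoised or untrained data and should carry no evidence either way.
#'
#' @param x,y numeric vectors of equal length.
#' @return a single number in \[-1, 1\].
#' @examples
#' dotsim(c(1, 1, -1), c(1, 1, -1))   # 1
#' dotsim(c(1, 1), c(-1, -1))         # -1
#' @export
dotsim <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dotsim: vectors must have equal lengths")
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Extract one mark's weight row from a signature
#'
#' Returns the `n_lines` weights of a single mark in genomic column order,
#' independent of the flatten order used during training.
#'
#' @param signature a `hebb_signature`.
#' @param mark mark name.
#' @return numeric vector of length `n_lines`.
#' @export
mark_subvector <- function(signature, mark) {
  m <- signature_matrix(signature)
  if (!mark %in% rownames(m)) {
    stop("unknown mark '", mark, "'; available: ",
         paste(rownames(m), collapse = ", "))
  }
  m[mark, ]
}

#' Compare two chromatin signatures quantitatively
#'
#' Computes the whole-vector [dotsim()] plus a per-mark dotsim over each
#' mark's weight row. A mark is flagged `common` when its similarity is at
#' least `tau`, `opposite` at or below `-tau`, and `inconsistent` in between
#' (including zero-norm rows) -- inconsistent marks should not drive the
#' comparison of the two region sets.
#'
#' @param s1,s2 `hebb_signature` objects over the same marks and line count.
#' @param tau classification threshold in (0, 1\] (default 0.5).
#' @return a `signature_comparison`: list with `overall` (whole-vector
#'   dotsim) and `marks` (data.frame: mark, dotsim, flag).
#' @export
compare_signatures <- function(s1, s2, tau = 0.5) {
  stopifnot(inherits(s1, "hebb_signature"), inherits(s2, "hebb_signature"),
            tau > 0, tau <= 1)
  d <- c(setdiff(s1$mark_names, s2$mark_names),
         setdiff(s2$mark_names, s1$mark_names))
  if (length(d)) {
    stop("signatures disagree on marks: ", paste(unique(d), collapse = ", "))
  }
  if (s1$n_lines != s2$n_lines) {
    stop("signatures have different line counts")
  }
  per_mark <- vapply(s1$mark_names, function(mk) {
    dotsim(mark_subvector(s1, mk), mark_subvector(s2, mk))
  }, numeric(1))
  flag <- ifelse(per_mark >= tau, "common",
                 ifelse(per_mark <= -tau, "opposite", "inconsistent"))
  structure(list(overall = dotsim(s1$weights, s2$weights),
                 marks = data.frame(mark = s1$mark_names,
                                    dotsim = unname(per_mark),
                                    flag = unname(flag)),
                 tau = tau),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("whole-vector dotsim: %.4f  (tau = %g)\n", x$overall, x$tau))
  print(x$marks, row.names = FALSE)
  invisible(x)
}

#' Directional preference of a mark around its regions
#'
#' Compares the learned profile of a mark over the upstream third of the
#' region (the first `floor(n/3)` line columns) with its profile over the
#' downstream third (the last `floor(n/3)` columns) by [dotsim()]. A negative
#' similarity means the mark stretches to one side -- it is directional.
#' Note the thirds are taken in the signature's stored column order: for
#' signatures trained on minus-strand regions without strand orientation,
#' genomic "upstream" is the right-hand side, so call this per strand group.
#'
#' @param signature a `hebb_signature` with at least 6 lines.
#' @param mark mark name.
#' @return list with `mark`, `dotsim` (upstream vs downstream thirds) and
#'   `directional` (`dotsim < 0`).
#' @export
mark_directionality <- function(signature, mark) {
  n <- signature$n_lines
  if (n < 6) stop("directionality needs at least 6 lines")
  row <- mark_subvector(signature, mark)
  t3 <- n %/% 3L
  val <- dotsim(row[seq_len(t3)], row[seq.int(n - t3 + 1L, n)])
  list(mark = mark, dotsim = val, directional = val < 0)
}

#' Percentage of tissues in which a mark is directional
#'
#' Across a collection of per-tissue signatures, counts the tissues where the
#' mark is known (present in the signature) and where it is directional per
#' [mark_directionality()]. The percentage is reported (rounded to integer
#' percent) only when the mark is known in at least `min_known` tissues,
#' otherwise `NA`.
#'
#' @param signatures list of `hebb_signature` objects, one per tissue.
#' @param mark mark name.
#' @param min_known minimum tissues for a reportable percentage (default 5).
#' @return list with `known`, `directional` counts and `percentage`.
#' @export
directional_percentage <- function(signatures, mark, min_known = 5L) {
  has <- vapply(signatures, function(s) mark %in% s$mark_names, logical(1))
  known <- sum(has)
  dir_n <- sum(vapply(signatures[has], function(s) {
    mark_directionality(s, mark)$directional
  }, logical(1)))
  pct <- if (known >= min_known) round_half_away(100 * dir_n / known)
         else NA_real_
  list(known = known, directional = dir_n, percentage = pct)
}

#' Average per-mark similarity across paired signatures
#'
#' For paired signatures (e.g. high- vs low-CpG promoters of the same
#' tissue), computes the per-tissue dotsim of one mark's rows and averages
#' over the tissues where both members of the pair know the mark. Strongly
#' negative averages single out marks distributed differently between the
#' two conditions.
#'
#' @param pairs list of length-2 lists of `hebb_signature` objects.
#' @param mark mark name.
#' @return list with `known` (tissue count) and `mean_dotsim`.
#' @export
average_mark_dotsim <- function(pairs, mark) {
  vals <- unlist(lapply(pairs, function(pr) {
    s1 <- pr[[1]]; s2 <- pr[[2]]
    if (mark %in% s1$mark_names && mark %in% s2$mark_names) {
      dotsim(mark_subvector(s1, mark), mark_subvector(s2, mark))
    } else {
      NULL
    }
  }))
  list(known = length(vals),
       mean_dotsim = if (length(vals)) mean(vals) else NA_real_)
}
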