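# small helper: signature object straight from a weight matrix
sig_from_matrix <- function(W, order = "column") {
  structure(list(weights = flatten_matrix(W, order),
                 mark_names = rownames(W), n_lines = ncol(W),
                 flatten_order = order, alpha = 0.1, epochs = 1L,
                 shuffle = FALSE, seed = 1L, n_regions = 0L),
            class = "hebb_signature")
}

test_that("dotsim matches the normalised dot product on worked cases", {
  expect_equal(dotsim(c(1, 1, -1), c(1, 1, -1)), 1)
  expect_equal(dotsim(c(1, 1), c(-1, -1)), -1)
  expect_equal(dotsim(c(1, 0, -1), c(1, 1, 1)), 0)
  expect_equal(dotsim(rep(0, 3), c(1, 1, 1)), 0)  # zero-norm convention
  expect_error(dotsim(c(1, 2), c(1, 2, 3)), "length")
})

test_that("dotsim is symmetric, scale-invariant and bounded", {
  withr::with_seed(61, {
    for (rep in 1:200) {
      n <- sample(2:50, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      d <- dotsim(x, y)
      expect_equal(d, dotsim(y, x))
      expect_equal(dotsim(runif(1, 0.1, 10) * x, y), d, tolerance = 1e-12)
      expect_true(d >= -1 - 1e-12 && d <= 1 + 1e-12)
    }
  })
})

test_that("mark_subvector recovers rows under either flatten order", {
  W <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("H3K4me3", "H3K9ac", "H2A.Z"), NULL))
  for (ord in c("column", "row")) {
    s <- sig_from_matrix(W, ord)
    for (mk in rownames(W)) {
      expect_equal(mark_subvector(s, mk), W[mk, ])
    }
  }
  expect_error(mark_subvector(sig_from_matrix(W), "H3K36me3"), "H3K9ac")
})

test_that("compare_signatures classifies common, opposite and inconsistent marks", {
  W <- matrix(c(rep(1, 4), rep(-1, 4), 1, 1, -1, -1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  s <- sig_from_matrix(W)
  same <- compare_signatures(s, s)
  expect_equal(same$overall, 1)
  expect_true(all(same$marks$flag == "common"))
  expect_true(all(same$marks$dotsim == 1))

  neg <- sig_from_matrix(-W)
  opp <- compare_signatures(s, neg)
  expect_equal(opp$overall, -1)
  expect_true(all(opp$marks$flag == "opposite"))

  Wz <- W
  Wz["b", ] <- 0
  zr <- compare_signatures(sig_from_matrix(Wz), s)
  expect_equal(zr$marks$dotsim[zr$marks$mark == "b"], 0)
  expect_equal(zr$marks$flag[zr$marks$mark == "b"], "inconsistent")

  W2 <- W
  rownames(W2) <- c("a", "b", "x")
  expect_error(compare_signatures(s, sig_from_matrix(W2)), "x")
})

test_that("directionality compares upstream and downstream thirds", {
  W <- rbind(mirror = c(1, 1, 1, 0, 0, 0, -1, -1, -1),
             flat = rep(1, 9),
             scaled = c(1, 1, 1, 0, 0, 0, 0.5, 0.5, 0.5))
  s <- sig_from_matrix(W)
  d1 <- mark_directionality(s, "mirror")
  expect_equal(d1$dotsim, -1)
  expect_true(d1$directional)
  d2 <- mark_directionality(s, "flat")
  expect_equal(d2$dotsim, 1)
  expect_false(d2$directional)
  # positive scaling does not create directionality
  d3 <- mark_directionality(s, "scaled")
  expect_equal(d3$dotsim, 1)
  expect_false(d3$directional)
  few <- sig_from_matrix(matrix(1, 1, 5, dimnames = list("m", NULL)))
  expect_error(mark_directionality(few, "m"), "6 lines")
})

test_that("directionality is invariant to consistent strand reversal", {
  withr::with_seed(62, {
    W <- matrix(sample(c(-1, 1), 2 * 9, replace = TRUE), 2, 9,
                dimnames = list(c("m1", "m2"), NULL))
    fwd <- sig_from_matrix(W)
    rev_ <- sig_from_matrix(W[, 9:1])
    for (mk in c("m1", "m2")) {
      a <- mark_directionality(fwd, mk)$dotsim
      b <- mark_directionality(rev_, mk)$dotsim
      expect_equal(a, b)  # thirds swap roles but dotsim is symmetric
    }
  })
})

test_that("directional percentages follow the at-least-five-tissues rule", {
  up <- c(1, 1, 1, 0, 0, 0, -1, -1, -1)   # directional row
  flat <- rep(1, 9)
  mk_sig <- function(dir) {
    W <- rbind(H3K4me3 = if (dir) up else flat)
    sig_from_matrix(W)
  }
  sigs <- c(lapply(1:41, function(i) mk_sig(TRUE)),
            lapply(1:16, function(i) mk_sig(FALSE)))
  res <- directional_percentage(sigs, "H3K4me3")
  expect_equal(res$known, 57)
  expect_equal(res$directional, 41)
  expect_equal(res$percentage, 72)   # 71.9 rounds to the printed integer
  # below the reporting floor
  res4 <- directional_percentage(sigs[1:4], "H3K4me3")
  expect_equal(res4$known, 4)
  expect_true(is.na(res4$percentage))
  # never-directional marks give 0
  res0 <- directional_percentage(sigs[42:57], "H3K4me3")
  expect_equal(res0$percentage, 0)
})

test_that("average_mark_dotsim averages over tissues that know the mark", {
  W1 <- matrix(c(1, 1, -1, 1), 1, 4, dimnames = list("m", NULL))
  s <- sig_from_matrix(W1)
  sneg <- sig_from_matrix(-W1)
  expect_equal(average_mark_dotsim(list(list(s, s), list(s, s)), "m"),
               list(known = 2, mean_dotsim = 1))
  expect_equal(average_mark_dotsim(list(list(s, sneg)), "m")$mean_dotsim, -1)
  # mean of 0.2 and -0.6 is -0.2: build pairs with those exact similarities
  a <- sig_from_matrix(matrix(c(1, 0, 0, 0, 0), 1, dimnames = list("m", NULL)))
  b1 <- sig_from_matrix(matrix(c(0.2, sqrt(1 - 0.04), 0, 0, 0), 1,
                               dimnames = list("m", NULL)))
  b2 <- sig_from_matrix(matrix(c(-0.6, sqrt(1 - 0.36), 0, 0, 0), 1,
                               dimnames = list("m", NULL)))
  res <- average_mark_dotsim(list(list(a, b1), list(a, b2)), "m")
  expect_equal(res$mean_dotsim, -0.2)
  # unknown mark in some tissues is skipped
  other <- sig_from_matrix(matrix(1, 1, 4, dimnames = list("x", NULL)))
  res2 <- average_mark_dotsim(list(list(s, s), list(other, other)), "m")
  expect_equal(res2$known, 1)
})
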