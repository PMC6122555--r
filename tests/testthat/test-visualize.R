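test_that("cityblock distance on worked cases", {
  expect_equal(cityblock(c(1, -1), c(1, 1)), 2)
  expect_equal(cityblock(c(0.3, -0.2), c(0.3, -0.2)), 0)
  expect_equal(cityblock(c(1, 0, -1), c(-1, 0, 1)), 4)
  expect_error(cityblock(1:2, 1:3), "length")
})

test_that("wpgma reproduces the hand-worked three-item linkage", {
  D <- matrix(c(0, 2, 8,
                2, 0, 6,
                8, 6, 0), 3, 3)
  dend <- wpgma(as.dist(D))
  expect_equal(dend$merges$height, c(2, 7))      # (A,B) at 2, then (8+6)/2
  expect_equal(unlist(dend$merges[1, 1:2]), c(a = 1, b = 2))
  # root children are (leaf 3, cluster 4); lower index first
  expect_equal(dend$leaf_order, c(3, 1, 2))
})

test_that("two items merge at their distance; one item has no merges", {
  d2 <- wpgma(as.dist(matrix(c(0, 5, 5, 0), 2)))
  expect_equal(d2$merges$height, 5)
  d1 <- wpgma(matrix(1:4, 1), labels = "only")
  expect_equal(nrow(d1$merges), 0)
  expect_equal(d1$leaf_order, 1L)
})

test_that("equal distances resolve by the lexicographic tie-break", {
  D <- matrix(3, 4, 4) - diag(3, 4)
  dend <- wpgma(as.dist(D))
  # (1,2) first, then (3,4), then the two pairs
  expect_equal(unname(as.matrix(dend$merges[, 1:2])),
               matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE))
  expect_equal(dend$merges$height, c(3, 3, 3))
  expect_equal(dend$leaf_order, 1:4)
})

test_that("wpgma agrees with the recursive tree-distance oracle", {
  withr::with_seed(71, {
    for (rep in 1:20) {
      k <- 6
      D <- matrix(0, k, k)
      D[upper.tri(D)] <- runif(k * (k - 1) / 2, 1, 20)
      D <- D + t(D)
      got <- wpgma(as.dist(D))
      want <- wpgma_oracle(D)
      expect_equal(got$merges$height, want$heights)
      expect_equal(unname(as.matrix(got$merges[, 1:2])), unname(want$pairs))
    }
  })
})

test_that("wpgma merge heights match hclust's mcquitty linkage", {
  withr::with_seed(72, {
    for (rep in 1:10) {
      k <- sample(4:8, 1)
      X <- matrix(rnorm(k * 5), k)
      D <- as.dist(sapply(seq_len(k), function(i) {
        sapply(seq_len(k), function(j) cityblock(X[i, ], X[j, ]))
      }))
      got <- wpgma(X)
      ref <- hclust(D, method = "mcquitty")
      expect_equal(got$merges$height, ref$height, tolerance = 1e-12)
    }
  })
})

test_that("rendering maps weights to the red/blue colour contract", {
  W <- matrix(c(1, -1, 0, 0.5), 2, 2,
              dimnames = list(c("m1", "m2"), NULL))
  sig <- structure(list(weights = flatten_matrix(W), mark_names = rownames(W),
                        n_lines = 2L, flatten_order = "column"),
                   class = "hebb_signature")
  img <- render_signature(sig, cell_px = 3)
  expect_equal(dim(img$pixels), c(6, 6, 3))
  px_of <- function(mark, col) {
    r <- 3 * (match(mark, img$row_labels) - 1) + 1
    c(img$pixels[r, 3 * (col - 1) + 1, ])
  }
  expect_equal(px_of("m1", 1), c(255, 0, 0))     # +1 -> pure red
  expect_equal(px_of("m2", 1), c(0, 0, 255))     # -1 -> pure blue
  expect_equal(px_of("m1", 2), c(128, 0, 127))   # 0 -> midpoint rounding
  # monotone in v: larger weight, at least as much red
  reds <- vapply(seq(-1, 1, by = 0.05), function(v) {
    Wv <- matrix(c(v, 1), 2, 1, dimnames = list(c("a", "b"), NULL))
    s <- structure(list(weights = flatten_matrix(Wv), mark_names = c("a", "b"),
                        n_lines = 1L, flatten_order = "column"),
                   class = "hebb_signature")
    d <- wpgma(Wv)
    im <- render_signature(s, dendrogram = d, cell_px = 1)
    im$pixels[match("a", im$row_labels), 1, 1]
  }, numeric(1))
  expect_true(all(diff(reds) >= 0))
})

test_that("renderer rejects a dendrogram over different marks", {
  W <- matrix(c(1, -1), 2, 1, dimnames = list(c("m1", "m2"), NULL))
  sig <- structure(list(weights = flatten_matrix(W), mark_names = rownames(W),
                        n_lines = 1L, flatten_order = "column"),
                   class = "hebb_signature")
  bad <- wpgma(matrix(c(0, 1), 2, 1), labels = c("x", "y"))
  expect_error(render_signature(sig, dendrogram = bad), "marks")
})

test_that("average_profile is the componentwise mean", {
  v <- c(1, -1, 1)
  expect_equal(average_profile(rbind(v, v, v)), c(v = c(1, -1, 1)),
               ignore_attr = TRUE)
  expect_equal(average_profile(rbind(c(1, 1), c(-1, -1))), c(0, 0))
  expect_equal(average_profile(rbind(c(1, 1, 1), c(1, -1, 1), c(1, -1, -1))),
               c(1, -1 / 3, 1 / 3))
  expect_error(average_profile(matrix(numeric(0), 0, 3)), "empty")
})

test_that("average profile of noisy planted vectors approaches (1-2p) pattern", {
  withr::with_seed(73, {
    pattern <- c(rep(1, 5), rep(-1, 5))
    p <- 0.15
    n <- 4000
    flips <- matrix(runif(n * 10) < p, n, 10)
    x <- matrix(rep(pattern, each = n), n, 10) * ifelse(flips, -1, 1)
    prof <- average_profile(x)
    expect_equal(prof, (1 - 2 * p) * pattern, tolerance = 0.1)
  })
})

test_that("region clustering pairs duplicate regions first", {
  withr::with_seed(74, {
    base <- matrix(sample(c(-1, 1), 3 * 8, replace = TRUE), 3, 8)
    x <- rbind(base, base)   # duplicates at distance 0
    dend <- cluster_regions(x)
    expect_equal(dend$merges$height[1:3], c(0, 0, 0))
    first3 <- as.matrix(dend$merges[1:3, 1:2])
    expect_equal(unname(first3), cbind(1:3, 4:6))
    two <- cluster_regions(rbind(base[1, ], base[1, ]))
    expect_equal(two$merges$height, 0)
  })
})

test_that("dendrograms export to parseable Newick with merge heights", {
  W <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(paste0("H3K", 1:4), NULL))
  dend <- wpgma(W)
  nwk <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), sort(rownames(W)))
  # tip depth is half the last merge height (as.phylo halves hclust heights)
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths), max(dend$merges$height) / 2, tolerance = 1e-6)
  f <- tempfile(fileext = ".nwk")
  dendrogram_newick(dend, f)
  expect_equal(ape::read.tree(f)$tip.label, phy$tip.label)
})
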