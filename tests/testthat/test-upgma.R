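test_that("a two-leaf tree is a cherry at half the distance", {
  d <- matrix(c(0, .6, .6, 0), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  tr <- upgma(d)
  expect_equal(tr$height, 0.6)
  expect_identical(toNewick(tr), "(A:0.3,B:0.3);")
})

test_that("the three-leaf worked example merges at hand-computed heights", {
  d <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(tr$height, c(0.2, 0.8))
  cp <- as.matrix(cophenetic(tr))
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.8)
  # Newick branch lengths follow the merge-distance/2 convention
  phy <- ape::read.tree(text = toNewick(tr))
  expect_equal(as.matrix(cophenetic(phy))[c("A", "B", "C"),
                                          c("A", "B", "C")], cp)
})

test_that("input validation rejects malformed distance matrices", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(neg), "negative")
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
})

test_that("cophenetic output agrees with average-linkage hclust", {
  set.seed(31)
  for (i in 1:20) {
    m <- random_dissimilarity(sample(5:8, 1))
    mine <- as.matrix(cophenetic(upgma(m)))
    ref <- as.matrix(cophenetic(hclust(as.dist(m), method = "average")))
    expect_equal(mine[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-12)
  }
})

test_that("cophenetic distances are ultrametric on arbitrary input", {
  set.seed(37)
  m <- random_dissimilarity(7)
  cp <- as.matrix(cophenetic(upgma(m)))
  n <- nrow(cp)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- sort(c(cp[i, j], cp[i, k], cp[j, k]), decreasing = TRUE)
    expect_lte(trio[1], trio[2] + 1e-12)  # two largest are equal
  }
})

test_that("equal merge distances break ties toward the lowest index pair", {
  d <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- upgma(d)
  expect_identical(tr$merge[1, ], c(-1L, -2L))  # A with B first
  expect_identical(upgma(d)$merge, tr$merge)    # and deterministically so
})

test_that("Newick round-trips preserve the cophenetic matrix", {
  set.seed(41)
  m <- random_dissimilarity(6)
  tr <- upgma(m)
  phy <- ape::read.tree(text = toNewick(tr))
  expect_equal(as.matrix(cophenetic(phy))[rownames(m), colnames(m)],
               as.matrix(cophenetic(tr))[rownames(m), colnames(m)],
               tolerance = 1e-9)
})

test_that("bootstrap supports are reproducible, bounded, and rooted at 100", {
  set.seed(1)
  bin <- random_presence(5, 30)
  t1 <- bootstrapSupport(bin, n_iter = 100, seed = 9)
  t2 <- bootstrapSupport(bin, n_iter = 100, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  root_clade <- paste(sort(t1$tip.label), collapse = "\r")
  pp <- ape::prop.part(t1)
  root_idx <- which(vapply(pp, length, 1L) == length(t1$tip.label))
  expect_equal(t1$node.label[root_idx], 100)
})

test_that("n_iter = 0 returns the tree without supports", {
  set.seed(2)
  phy <- bootstrapSupport(random_presence(4, 20), n_iter = 0)
  expect_null(phy$node.label)
  expect_s3_class(phy, "phylo")
})

test_that("an identical-species pair among distant samples gets full support", {
  bin <- rbind(s1 = c(1, 1, 1, 0, 0, 0, 0, 0),
               s2 = c(1, 1, 1, 0, 0, 0, 0, 0),
               s3 = c(0, 0, 0, 1, 1, 0, 0, 0),
               s4 = c(0, 0, 0, 0, 0, 1, 1, 1))
  phy <- bootstrapSupport(bin, n_iter = 200, seed = 5)
  pp <- ape::prop.part(phy)
  cherry <- which(vapply(pp, function(tips)
    setequal(phy$tip.label[tips], c("s1", "s2")), TRUE))
  expect_equal(phy$node.label[cherry], 100)
})
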