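threeTaxon <- function() {
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  as.dist(m)
}

test_that("UPGMA reproduces the hand-worked three-taxon example", {
  tr <- upgmaTree(threeTaxon())
  expect_equal(tr$height, c(1, 3))   # A,B at d/2 = 1; root at 3
  cm <- as.matrix(copheneticDistance(tr))
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 6)
  expect_equal(cm["B", "C"], 6)
  cl <- cutClusters(tr, k = 2)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["A"]] == cl[["C"]])
})

test_that("two leaves merge at half their distance", {
  tr <- upgmaTree(dist(c(A = 0, B = 2)))
  expect_equal(tr$height, 1)
  expect_equal(sort(tr$labels), c("A", "B"))
})

test_that("cophenetic distances are a fixed point on ultrametric input", {
  tr <- upgmaTree(threeTaxon())
  co <- copheneticDistance(tr)
  tr2 <- upgmaTree(co)
  expect_equal(as.matrix(copheneticDistance(tr2)), as.matrix(co),
               tolerance = 1e-12)
})

test_that("average linkage agrees with hclust on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    d <- dist(matrix(rnorm(8 * 3), 8,
                     dimnames = list(paste0("t", 1:8), NULL)))
    tr <- upgmaTree(d)
    hc <- hclust(d, method = "average")
    # same merge heights (ours are halved) and same cophenetic structure
    expect_equal(sort(2 * tr$height), sort(hc$height), tolerance = 1e-9)
    expect_equal(as.matrix(copheneticDistance(tr))[tr$labels, tr$labels],
                 as.matrix(cophenetic(hc))[tr$labels, tr$labels],
                 tolerance = 1e-9)
  }
})

test_that("ties break deterministically by smallest leaf index", {
  # equilateral quartet: every pair at distance 4
  m <- matrix(4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  tr <- upgmaTree(as.dist(m))
  # first merge must be (a, b) = leaves 1 and 2
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))
  # repeated runs are identical
  expect_identical(upgmaTree(as.dist(m)), tr)
})

test_that("Newick export round-trips topology and heights", {
  set.seed(32)
  d <- dist(matrix(rnorm(6 * 3), 6,
                   dimnames = list(paste0("t", 1:6), NULL)))
  tr <- upgmaTree(d)
  f <- tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, paste0("t", 1:6))
  # path lengths in the tree equal cophenetic distances to 6 decimals
  co <- as.matrix(copheneticDistance(tr))
  pd <- ape::cophenetic.phylo(phy)[rownames(co), colnames(co)]
  expect_equal(round(pd, 6), round(co, 6))
  unlink(f)
})

test_that("invalid inputs are rejected", {
  m <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgmaTree(as.dist(m)), "NA")
  tr <- upgmaTree(threeTaxon())
  expect_error(cutClusters(tr, k = 9), "1..3")
  expect_error(cutClusters(tr), "supply")
})
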