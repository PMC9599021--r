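twoLocusTable <- function() {
  makeGenotypeTable(list(
    L1 = rbind(c(200, 204), c(200, 200)),
    L2 = rbind(c(300, 300), c(300, 300))
  ))
}

test_that("allele frequencies are count-based over typed calls", {
  x <- twoLocusTable()
  p <- alleleFrequencies(x, "L1")
  expect_equal(unname(p), c(0.75, 0.25))
  expect_equal(names(p), c("200", "204"))
  expect_equal(sum(p), 1)
  expect_equal(unname(alleleFrequencies(x, "L2")), 1)
  # all-missing locus errors
  xm <- makeGenotypeTable(list(L1 = rbind(c(NA, NA), c(NA, NA))))
  expect_error(alleleFrequencies(xm, "L1"), "missing")
})

test_that("He and PIC match hand arithmetic", {
  expect_equal(expectedHet(1), 0)
  expect_equal(expectedHet(c(0.5, 0.5)), 0.5)
  expect_equal(expectedHet(c(0.9, 0.1)), 0.18, tolerance = 1e-12)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375, tolerance = 1e-12)
  expect_equal(pic(c(0.9, 0.1)), 1 - 0.82 - 2 * 0.81 * 0.01, tolerance = 1e-12)
  expect_error(expectedHet(c(0.5, 0.4)), "sum to 1")
  # small-sample corrected variant
  expect_equal(expectedHet(c(0.5, 0.5), corrected = TRUE, n = 10),
               0.5 * 20 / 19, tolerance = 1e-12)
})

test_that("PIC equals the brute-force pair enumeration and PIC <= He", {
  set.seed(8)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    p <- as.numeric(rmultinom(1, 50, rep(1, k))) / 50
    p <- p[p > 0]
    if (length(p) < 2) next
    expect_equal(pic(p), picOracle(p), tolerance = 1e-12)
    expect_lt(pic(p), expectedHet(p))
    expect_lte(expectedHet(p), 1 - 1 / length(p) + 1e-12)
  }
})

test_that("observed heterozygosity counts typed heterozygotes only", {
  x <- makeGenotypeTable(list(
    L1 = rbind(c(200, 204), c(200, 200), c(NA, NA))
  ))
  expect_equal(observedHet(x, "L1"), 0.5)
  st <- locusStats(x)
  expect_equal(st$nTyped, 2L)
  expect_equal(st$nAlleles, 2L)
})

test_that("per-locus statistics and summaries line up", {
  x <- twoLocusTable()
  st <- locusStats(x)
  expect_equal(st$He[st$locus == "L1"], expectedHet(c(0.75, 0.25)))
  expect_equal(st$Ho[st$locus == "L1"], 0.5)
  expect_false(st$polymorphic[st$locus == "L2"])
  # monomorphic locus has zero diversity and drops from the summary
  expect_equal(st$He[st$locus == "L2"], 0)
  expect_equal(st$PIC[st$locus == "L2"], 0)
  sm <- summarizeLoci(st)
  expect_equal(sm$nLoci, 1L)
  expect_equal(sm$meanHe, st$He[st$locus == "L1"])
  sm2 <- summarizeLoci(st, polymorphicOnly = FALSE)
  expect_equal(sm2$nLoci, 2L)
  expect_equal(sm2$totalAlleles, 3)
  # single-locus summary equals that locus
  one <- summarizeLoci(st[st$locus == "L1", ])
  expect_equal(one$meanPIC, st$PIC[st$locus == "L1"])
})

test_that("He/Ho estimates recover truth under simulated HWE", {
  cfg <- simulationConfig()
  x <- simulateGenotypes(cfg, seed = 101)
  st <- locusStats(x)
  # n = 25 genotypes: coarse agreement only (3 SE binomial-ish)
  for (l in names(cfg$lociSpec)) {
    he <- expectedHet(cfg$lociSpec[[l]]$freqs)
    expect_lt(abs(st$He[st$locus == l] - he), 3 * sqrt(he * (1 - he) / 25) + 0.02)
  }
})
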