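test_that("group summaries give mean and SE = sd/sqrt(n)", {
  reps <- data.frame(genotype = rep(c("a", "b"), each = 3),
                     variable = "TPC",
                     value = c(10, 10, 10, 1, 2, 3))
  s <- summarizeGroups(reps)
  expect_equal(s$mean[s$genotype == "a"], 10)
  expect_equal(s$se[s$genotype == "a"], 0)
  expect_equal(s$mean[s$genotype == "b"], 2)
  expect_equal(s$se[s$genotype == "b"], 1 / sqrt(3), tolerance = 1e-12)
  # single replicate: SE undefined, reported missing
  s1 <- summarizeGroups(data.frame(genotype = "a", variable = "x", value = 5))
  expect_true(is.na(s1$se))
  expect_equal(s1$n, 1L)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups (1,2,3) and (4,5,6): SSB = 13.5, SSW = 4, df (1,4), F = 13.5
  av <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(av$ssBetween, 13.5)
  expect_equal(av$ssWithin, 4)
  expect_equal(av$dfBetween, 1)
  expect_equal(av$dfWithin, 4)
  expect_equal(av$F, 13.5)
  expect_equal(av$mse, 1)
  # identical groups: F = 0
  av0 <- oneWayAnova(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(av0$F, 0)
  expect_error(oneWayAnova(c(1, 2, 3), c("A", "A", "B")), "n >= 2")
})

test_that("ANOVA type-I error rate is nominal under the null", {
  set.seed(2024)
  nsim <- 2000
  rej <- logical(nsim)
  g <- rep(letters[1:5], each = 3)
  for (i in seq_len(nsim)) {
    rej[i] <- oneWayAnova(rnorm(15), g)$p <= 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Pearson matrix reproduces hand covariances and handles degeneracy", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6), z = c(1, 3, 2))
  r <- pearsonMatrix(d)
  expect_equal(unname(r["x", "y"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["x", "z"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_warning(r0 <- pearsonMatrix(data.frame(x = c(1, 2, 3), c0 = c(5, 5, 5))),
                 "zero variance")
  expect_true(is.na(r0["x", "c0"]))
  expect_error(pearsonMatrix(d[1:2, ]), "at least 3")
})

test_that("Pearson r is invariant under positive affine maps, flips sign under negative", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  d <- data.frame(x = x, y = y)
  r <- pearsonMatrix(d)["x", "y"]
  d2 <- data.frame(x = 3 * x + 7, y = 0.5 * y - 2)
  expect_equal(pearsonMatrix(d2)["x", "y"], r, tolerance = 1e-12)
  d3 <- data.frame(x = -2 * x, y = y)
  expect_equal(pearsonMatrix(d3)["x", "y"], -r, tolerance = 1e-12)
})

test_that("fold range and grand mean behave per contract", {
  expect_equal(rangeRatio(c(4, 4, 4)), 1)
  expect_equal(rangeRatio(c(2, 10)), 5)
  expect_error(rangeRatio(c(0, 1)), "positive")
  expect_equal(grandMean(42), 42)
  expect_error(grandMean(numeric(0)), "empty")
})
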