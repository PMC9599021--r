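test_that("zero CV reproduces the truth table exactly", {
  cfg <- simulationConfig(nGenotypes = 5, cv = 0)
  sim <- simulateAssays(cfg, seed = 1)
  for (i in seq_len(nrow(sim$replicates))) {
    expect_equal(sim$replicates$value[i],
                 sim$truth[sim$replicates$genotype[i],
                           sim$replicates$variable[i]])
  }
})

test_that("a fixed seed gives identical output, different seeds differ", {
  cfg <- simulationConfig(nGenotypes = 5)
  a <- simulateStudy(cfg, seed = 12)
  b <- simulateStudy(cfg, seed = 12)
  expect_identical(a$replicates, b$replicates)
  expect_identical(alleleCalls(a$genotypes, "RiMY01"),
                   alleleCalls(b$genotypes, "RiMY01"))
  c <- simulateStudy(cfg, seed = 13)
  expect_false(identical(a$replicates$value, c$replicates$value))
})

test_that("simulated absorbance quantifies back to the replicate values", {
  cfg <- simulationConfig(nGenotypes = 6)
  sim <- simulateAssays(cfg, seed = 2)
  q <- suppressWarnings(quantifyAssays(sim$absorbance, sim$context))
  merged <- merge(q, sim$replicates,
                  by.x = c("genotype", "assay", "replicate"),
                  by.y = c("genotype", "variable", "replicate"))
  expect_equal(nrow(merged), nrow(sim$replicates))
  expect_lt(max(abs(merged$value.x - merged$value.y)), 1e-9)
})

test_that("HWE genotype draws recover the configured frequencies", {
  # single biallelic locus at 0.5/0.5, many genotypes
  gm <- berryAssayMeans()
  cfg <- simulationConfig(
    nGenotypes = 25,
    lociSpec = list(B = list(sizes = c(100L, 110L), freqs = c(0.5, 0.5))))
  # stack many independent draws to reach n = 1000 genotypes
  hets <- afreq <- numeric(40)
  for (i in 1:40) {
    x <- simulateGenotypes(cfg, seed = 500 + i)
    hets[i] <- observedHet(x, "B")
    afreq[i] <- alleleFrequencies(x, "B")[["100"]]
  }
  n <- 40 * 25
  # Ho under HWE: 2pq = 0.5, binomial SE over n genotypes
  expect_lt(abs(mean(hets) - 0.5), 3 * sqrt(0.25 / n))
  # allele frequency: SE over 2n draws
  expect_lt(abs(mean(afreq) - 0.5), 3 * sqrt(0.25 / (2 * n)))
  # monomorphic locus: every call homozygous
  cfg1 <- simulationConfig(
    nGenotypes = 10,
    lociSpec = list(M = list(sizes = 200L, freqs = 1)))
  x1 <- simulateGenotypes(cfg1, seed = 3)
  expect_equal(observedHet(x1, "M"), 0)
})

test_that("allele frequency estimates tighten as n grows", {
  spec <- defaultLociSpec()["FaFS01"]
  gm <- data.frame(genotype = paste0("G", 1:5000),
                   TPC = 200, TFC = 150, TAC = 30, FRAP = 25, ABTS = 35)
  err <- sapply(c(50, 500, 5000), function(n) {
    cfg <- simulationConfig(nGenotypes = n, genotypeMeans = gm[1:n, ],
                            lociSpec = spec)
    x <- simulateGenotypes(cfg, seed = 77)
    abs(alleleFrequencies(x, "FaFS01")[["258"]] - 0.728)
  })
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 0.01)
})

test_that("the association shifts designated trait truths by dosage", {
  cfg <- simulationConfig(nGenotypes = 24, effect = "strong")
  expect_equal(cfg$effect, 4)
  x <- simulateGenotypes(cfg, seed = 9)
  sim <- simulateAssays(cfg, genotypes = x, seed = 9)
  dose <- associationDosage(cfg, x)
  base <- as.matrix(cfg$genotypeMeans[, c("TPC", "TFC", "TAC", "FRAP", "ABTS")])
  rownames(base) <- as.character(cfg$genotypeMeans$genotype)
  for (tr in c("TPC", "TFC", "FRAP", "ABTS")) {
    expect_equal(sim$truth[, tr],
                 base[, tr] + 4 * dose[rownames(base)] * sd(base[, tr]))
  }
  # anthocyanins stay uncoupled
  expect_equal(sim$truth[, "TAC"], base[, "TAC"])
  # effect = 0 leaves every truth untouched
  cfg0 <- simulationConfig(nGenotypes = 24, effect = 0)
  sim0 <- simulateAssays(cfg0, genotypes = x, seed = 9)
  expect_equal(sim0$truth, base)
})

test_that("null simulations give null-distributed Mantel p-values", {
  rates <- numeric(120)
  for (i in seq_len(120)) {
    cfg <- simulationConfig(nGenotypes = 15, effect = 0)
    st <- simulateStudy(cfg, seed = 9000 + i)
    md <- replicateMeans(st$replicates)
    mt <- mantelTest(biochemDistance(md),
                     geneticDistance(st$genotypes, "shared_allele"),
                     nPerm = 99, seed = i)
    rates[i] <- mt@pValue
  }
  expect_gte(mean(rates <= 0.05), 0.0)
  expect_lte(mean(rates <= 0.05), 0.12)
  expect_gt(mean(rates <= 0.5), 0.38)
  expect_lt(mean(rates <= 0.5), 0.62)
})

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(cv = -0.1), "cv")
  expect_error(simulationConfig(nGenotypes = 1), ">= 2")
  expect_error(simulationConfig(nGenotypes = 26), "exceeds")
  expect_error(simulationConfig(
    lociSpec = list(L = list(sizes = c(1L, 2L), freqs = c(0.6, 0.6)))),
    "sum to 1")
  expect_error(simulationConfig(associationTraits = "XYZ"), "unknown assay")
})
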