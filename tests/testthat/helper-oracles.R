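# Shared fixtures and independent oracles used across test files.

# three replicate values with exactly the requested sample mean and sd
exactReplicates <- function(m, s) m + s * c(-1, 0, 1)

# long replicate table with exact genotype means/sds for one variable
exactReplicateTable <- function(means, sds, variable = "TPC") {
  do.call(rbind, lapply(seq_along(means), function(i) {
    data.frame(genotype = names(means)[i], variable = variable,
               replicate = 1:3,
               value = exactReplicates(means[i], sds[i]),
               stringsAsFactors = FALSE)
  }))
}

# brute-force PIC: direct double sum over allele pairs
picOracle <- function(p) {
  k <- length(p)
  s <- 1 - sum(p^2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) s <- s - 2 * p[i]^2 * p[j]^2
  }
  s
}

# brute-force Duncan significance: a pair of ranked means is significant
# iff EVERY range containing it exceeds that range's critical value
# (direct containment enumeration, no interval bookkeeping).
duncanOracleSig <- function(meansSorted, Rp) {
  k <- length(meansSorted)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- TRUE
    for (a in 1:i) for (b in j:k) {
      span <- b - a + 1
      if (!(meansSorted[a] - meansSorted[b] > Rp[as.character(span)])) {
        ok <- FALSE
      }
    }
    sig[i, j] <- sig[j, i] <- ok
  }
  sig
}

# a compact-letter display is consistent with a significance matrix iff
# significant pairs share no letter and non-significant pairs share >= 1
cldConsistent <- function(letters, sig) {
  k <- length(letters)
  chars <- lapply(strsplit(letters, ""), unique)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(chars[[i]], chars[[j]])) > 0
    if (sig[i, j] && share) return(FALSE)
    if (!sig[i, j] && !share) return(FALSE)
  }
  TRUE
}

# small labelled genotype table from a list of (a1, a2) call matrices
makeGenotypeTable <- function(calls) {
  # calls: list locus -> 2-column matrix of allele sizes (NA = missing)
  n <- nrow(calls[[1]])
  gn <- paste0("g", seq_len(n))
  a1 <- sapply(calls, function(m) as.integer(m[, 1]))
  a2 <- sapply(calls, function(m) as.integer(m[, 2]))
  if (n == 1L) { a1 <- t(a1); a2 <- t(a2) }
  dimnames(a1) <- dimnames(a2) <- list(gn, names(calls))
  SSRGenotypeTable(a1, a2)
}

# genotype x assay means table from simulated replicates
replicateMeans <- function(replicates) {
  s <- summarizeGroups(replicates)
  md <- do.call(rbind, lapply(split(s, s$genotype), function(d)
    setNames(d$mean, d$variable)))
  data.frame(genotype = rownames(md), md, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# random labelled distance matrix on n objects (points in R^dim)
randomDist <- function(n, dim = 3) {
  m <- matrix(rnorm(n * dim), n)
  rownames(m) <- paste0("g", seq_len(n))
  dist(m)
}
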