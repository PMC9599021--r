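# run expr with a local, restorable RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(list = ".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Default SSR locus specification
#'
#' Seven polymorphic microsatellite loci mirroring the allele counts of the
#' study panel (2, 3, 2, 2, 3, 7, 2 alleles), with fragment sizes in the
#' 200-400 bp range and allele frequencies chosen to reproduce the
#' panel's per-locus expected heterozygosities (0.12-0.82). Frequencies
#' are deliberately non-uniform, as in real germplasm.
#'
#' @return named list; each element has \code{sizes} (bp) and \code{freqs}
#'   (simplex).
#' @export
defaultLociSpec <- function() {
  list(
    RcFH01 = list(sizes = c(212L, 218L), freqs = c(0.938, 0.062)),
    FaFH01 = list(sizes = c(231L, 237L, 243L), freqs = c(0.895, 0.070, 0.035)),
    FaFS01 = list(sizes = c(258L, 264L), freqs = c(0.728, 0.272)),
    RiAS01 = list(sizes = c(285L, 291L), freqs = c(0.895, 0.105)),
    RhUF01 = list(sizes = c(301L, 305L, 309L), freqs = c(0.915, 0.060, 0.025)),
    RiMY01 = list(sizes = c(320L, 326L, 332L, 338L, 344L, 350L, 356L),
                  freqs = c(0.30, 0.18, 0.15, 0.12, 0.10, 0.09, 0.06)),
    RiG001 = list(sizes = c(372L, 378L), freqs = c(0.913, 0.087))
  )
}

#' Simulation configuration
#'
#' Bundles everything the generator needs: the genotype truth table for the
#' five assays (defaults to the packaged panel means), the replicate design
#' (n = 3 with multiplicative noise of CV 0.08, matching the magnitude of
#' the published standard errors), the SSR locus spec, and an optional
#' genetic-biochemical association.
#'
#' The association couples the dosage (0/1/2 copies) of one designated
#' allele to a coherent shift of the phenolic-pool traits (by default TPC,
#' TFC, FRAP and ABTS — these co-vary strongly in real germplasm, so a
#' pathway allele moves them together; anthocyanins are a distinct sub-pool
#' and are left uncoupled): \code{shift = effect * dosage * sd(trait
#' means)}. \code{effect} accepts a number or a preset name: \code{"none"}
#' (0), \code{"moderate"} (2) or \code{"strong"} (4). The strong preset is
#' a major-gene effect of the kind seen for pathway loss-of-function
#' alleles.
#'
#' @param nGenotypes number of genotypes (default 25; up to the rows of
#'   \code{genotypeMeans}).
#' @param nReplicates replicates per genotype per assay (default 3).
#' @param cv replicate coefficient of variation (default 0.08).
#' @param genotypeMeans data frame with columns genotype, TPC, TFC, TAC,
#'   FRAP, ABTS (means); default [berryAssayMeans()].
#' @param lociSpec locus specification, see [defaultLociSpec()].
#' @param associationLocus,associationAllele designated locus and allele
#'   size for the association (defaults: FaFS01 allele 264).
#' @param associationTraits assay truths shifted by the allele dosage.
#' @param effect association effect size in SD-of-genotype-means per allele
#'   copy (default 0 = no association), or a preset name
#'   ("none"/"moderate"/"strong").
#' @return list of class \code{"phenodiv_config"}.
#' @export
simulationConfig <- function(nGenotypes = 25, nReplicates = 3, cv = 0.08,
                             genotypeMeans = NULL,
                             lociSpec = defaultLociSpec(),
                             associationLocus = "FaFS01",
                             associationAllele = 264L,
                             associationTraits = c("TPC", "TFC", "FRAP", "ABTS"),
                             effect = 0) {
  if (is.character(effect))
    effect <- switch(match.arg(effect, c("none", "moderate", "strong")),
                     none = 0, moderate = 2, strong = 4)
  if (is.null(genotypeMeans)) genotypeMeans <- berryAssayMeans()
  if (cv < 0) stop("'cv' must be >= 0")
  if (nReplicates < 1) stop("'nReplicates' must be >= 1")
  if (nGenotypes < 2) stop("'nGenotypes' must be >= 2")
  if (nGenotypes > nrow(genotypeMeans))
    stop("'nGenotypes' exceeds the rows of 'genotypeMeans'")
  for (l in names(lociSpec)) {
    sp <- lociSpec[[l]]
    if (length(sp$sizes) != length(sp$freqs))
      stop("locus ", l, ": sizes and freqs differ in length")
    .check_simplex(sp$freqs)
  }
  gm <- genotypeMeans[seq_len(nGenotypes), , drop = FALSE]
  if (!all(associationTraits %in% c("TPC", "TFC", "TAC", "FRAP", "ABTS")))
    stop("unknown assay in 'associationTraits'")
  structure(list(nGenotypes = nGenotypes, nReplicates = nReplicates,
                 cv = cv, genotypeMeans = gm, lociSpec = lociSpec,
                 associationLocus = associationLocus,
                 associationAllele = as.integer(associationAllele),
                 associationTraits = associationTraits,
                 effect = effect),
            class = "phenodiv_config")
}

#' Simulate diploid SSR genotypes under Hardy-Weinberg equilibrium
#'
#' For every genotype and locus two alleles are drawn independently from
#' the locus frequency vector; loci are unlinked.
#'
#' @param config a [simulationConfig()].
#' @param seed optional integer seed.
#' @return an [SSRGenotypeTable-class] with the config's genotype names.
#' @export
simulateGenotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phenodiv_config"))
  .withSeed(seed, {
    gnames <- as.character(config$genotypeMeans$genotype)
    loci <- names(config$lociSpec)
    draw <- function(sp)
      sp$sizes[sample.int(length(sp$sizes), config$nGenotypes,
                          replace = TRUE, prob = sp$freqs)]
    a1 <- vapply(config$lociSpec, draw, integer(config$nGenotypes))
    a2 <- vapply(config$lociSpec, draw, integer(config$nGenotypes))
    dimnames(a1) <- dimnames(a2) <- list(gnames, loci)
    SSRGenotypeTable(a1, a2)
  })
}

#' Dosage of the designated association allele
#'
#' @param config a [simulationConfig()].
#' @param genotypes an [SSRGenotypeTable-class].
#' @return integer vector (0, 1 or 2 copies) named by genotype.
#' @export
associationDosage <- function(config, genotypes) {
  calls <- alleleCalls(genotypes, config$associationLocus)
  (calls[, 1] == config$associationAllele) +
    (calls[, 2] == config$associationAllele)
}

# genotype x assay truth matrix, shifted by the association when genotypes
# are supplied and the effect is non-zero
.truthTable <- function(config, genotypes = NULL) {
  assays <- c("TPC", "TFC", "TAC", "FRAP", "ABTS")
  truth <- as.matrix(config$genotypeMeans[, assays])
  rownames(truth) <- as.character(config$genotypeMeans$genotype)
  if (!is.null(genotypes) && config$effect != 0) {
    dose <- associationDosage(config, genotypes)[rownames(truth)]
    for (tr in config$associationTraits) {
      truth[, tr] <- truth[, tr] + config$effect * dose * sd(truth[, tr])
    }
  }
  truth
}

#' Simulate replicate assay measurements and raw absorbance records
#'
#' Replicate values are drawn as \code{Normal(truth, cv * truth)} truncated
#' at zero (multiplicative noise, matching the roughly proportional
#' standard errors of the study design). The raw absorbance table is
#' obtained by pushing every replicate value backwards through the
#' quantification chain with the package's default calibration curves and
#' dilution factors, so [quantifyAssays()] run on the output recovers the
#' replicate values exactly — the two modules are exact inverses at
#' \code{cv = 0}.
#'
#' @param config a [simulationConfig()].
#' @param genotypes optional [SSRGenotypeTable-class]; when supplied and the
#'   config's \code{effect} is non-zero, truths are shifted by the
#'   designated allele dosage before noise is added.
#' @param seed optional integer seed.
#' @return list with elements \code{replicates} (genotype, variable,
#'   replicate, value), \code{absorbance} (long table consumable by
#'   [quantifyAssays()]), \code{truth} (genotype x assay matrix after any
#'   association shift) and \code{context} (one-row context table).
#' @export
simulateAssays <- function(config, genotypes = NULL, seed = NULL) {
  stopifnot(inherits(config, "phenodiv_config"))
  .withSeed(seed, {
    truth <- .truthTable(config, genotypes)
    assays <- colnames(truth)
    gnames <- rownames(truth)
    nR <- config$nReplicates

    grid <- expand.grid(replicate = seq_len(nR), genotype = gnames,
                        variable = assays, stringsAsFactors = FALSE)
    mu <- truth[cbind(grid$genotype, grid$variable)]
    if (config$cv == 0) {
      val <- mu
    } else {
      val <- rnorm(length(mu), mu, config$cv * mu)
      bad <- which(val < 0)
      tries <- 0
      while (length(bad) && tries < 100) {
        val[bad] <- rnorm(length(bad), mu[bad], config$cv * mu[bad])
        bad <- bad[val[bad] < 0]
        tries <- tries + 1
      }
      val[val < 0] <- 0
    }
    replicates <- data.frame(genotype = grid$genotype,
                             variable = grid$variable,
                             replicate = grid$replicate,
                             value = val, stringsAsFactors = FALSE)

    curves <- defaultCurves()
    dfs <- defaultDilutionFactors()
    sm <- 5; ev <- 30
    absorbance <- do.call(rbind, lapply(seq_len(nrow(replicates)), function(i) {
      g <- replicates$genotype[i]; a <- replicates$variable[i]
      rep_ <- replicates$replicate[i]; v <- replicates$value[i]
      df <- unname(dfs[a])
      rows <- switch(a,
        TPC = {
          conc <- v * 1000 / (df * ev * 100 / sm)
          c(A760 = curves$gallic_acid@slope * conc + curves$gallic_acid@intercept)
        },
        TFC = {
          conc <- v * 1000 / (df * ev * 100 / sm)
          c(A510 = curves$rutin@slope * conc + curves$rutin@intercept)
        },
        TAC = {
          mgL <- v / ((ev / 1000) * (100 / sm))
          A <- mgL * .TAC_EPSILON / (.TAC_MW * 1000 * df)
          c(A510_pH1 = A + 0.05, A700_pH1 = 0.02,
            A510_pH45 = 0.06, A700_pH45 = 0.03)
        },
        FRAP = {
          conc <- v * sm / (df * ev)
          c(A593 = curves$trolox_frap@slope * conc + curves$trolox_frap@intercept)
        },
        ABTS = {
          conc <- v * sm / (df * ev)
          inh <- curves$trolox_abts@slope * conc + curves$trolox_abts@intercept
          c(A734_blank = 0.70, A734_sample = 0.70 * (1 - inh / 100))
        })
      data.frame(genotype = g, assay = a, replicate = rep_,
                 reading_name = names(rows), value = unname(rows),
                 dilution_factor = df, stringsAsFactors = FALSE)
    }))
    rownames(absorbance) <- NULL

    context <- data.frame(genotype = gnames, tissue = "berry",
                          sample_mass_g = sm, extract_volume_ml = ev,
                          stringsAsFactors = FALSE)
    list(replicates = replicates, absorbance = absorbance,
         truth = truth, context = context)
  })
}

#' Simulate a full two-domain study
#'
#' Genotypes first (so an association can act), then assays.
#'
#' @param config a [simulationConfig()].
#' @param seed optional integer seed controlling both stages.
#' @return list: \code{genotypes} ([SSRGenotypeTable-class]) plus all
#'   elements of [simulateAssays()].
#' @export
simulateStudy <- function(config, seed = NULL) {
  .withSeed(seed, {
    genotypes <- simulateGenotypes(config)
    c(list(genotypes = genotypes), simulateAssays(config, genotypes))
  })
}
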