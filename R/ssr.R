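#' Construct a diploid SSR genotype table
#'
#' @param a1,a2 integer matrices (genotypes x loci) of the two allele sizes
#'   per call, with genotype rownames and locus colnames; \code{NA} marks a
#'   missing call (both sizes must be \code{NA} together).
#' @return an [SSRGenotypeTable-class] object.
#' @examples
#' a1 <- matrix(c(200L, 200L), 2, 1,
#'              dimnames = list(c("g1", "g2"), "LocA"))
#' a2 <- matrix(c(204L, 200L), 2, 1,
#'              dimnames = list(c("g1", "g2"), "LocA"))
#' SSRGenotypeTable(a1, a2)
#' @export
SSRGenotypeTable <- function(a1, a2) {
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  new("SSRGenotypeTable", a1 = a1, a2 = a2)
}

#' Allele frequencies at one locus
#'
#' Count-based frequencies over the 2 x n_typed allele observations at the
#' locus; missing calls drop out of the denominator.
#'
#' @param x an [SSRGenotypeTable-class].
#' @param locus locus name or column index.
#' @return named numeric vector (names = allele sizes, ascending) summing
#'   to 1.
#' @export
alleleFrequencies <- function(x, locus) {
  calls <- alleleCalls(x, locus)
  obs <- c(calls[, 1], calls[, 2])
  obs <- obs[!is.na(obs)]
  if (!length(obs)) stop("all calls missing at locus ", locus)
  tab <- table(obs)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p[order(as.integer(names(p)))]
}

.check_simplex <- function(p, tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -tol))
    stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("allele frequencies must sum to 1 (got ", format(sum(p)), ")")
}

#' Expected heterozygosity (gene diversity)
#'
#' \eqn{He = 1 - \sum_i p_i^2}, the probability that two random alleles
#' differ. With \code{corrected = TRUE} the small-sample factor
#' \eqn{2n/(2n - 1)} is applied (unbiased gene diversity), where \code{n}
#' is the number of typed individuals.
#'
#' @param p allele frequency vector (a simplex).
#' @param corrected apply the small-sample correction (default FALSE,
#'   matching the plain gene-diversity definition).
#' @param n number of typed diploid individuals; required when
#'   \code{corrected = TRUE}.
#' @return He in [0, 1].
#' @export
expectedHet <- function(p, corrected = FALSE, n = NULL) {
  .check_simplex(p)
  he <- 1 - sum(p^2)
  if (corrected) {
    if (is.null(n)) stop("'n' (typed individuals) is required for the corrected estimator")
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' Observed heterozygosity at one locus
#'
#' Fraction of typed genotypes whose two alleles differ.
#'
#' @inheritParams alleleFrequencies
#' @return Ho in [0, 1].
#' @export
observedHet <- function(x, locus) {
  calls <- alleleCalls(x, locus)
  typed <- !is.na(calls[, 1])
  if (!any(typed)) stop("all calls missing at locus ", locus)
  mean(calls[typed, 1] != calls[typed, 2])
}

#' Polymorphic information content
#'
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}: expected
#' heterozygosity minus a correction for matings whose offspring are
#' uninformative; the standard measure of a codominant marker's
#' discriminating power.
#'
#' @inheritParams expectedHet
#' @return PIC in [0, 1).
#' @export
pic <- function(p) {
  .check_simplex(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - s4)
}

#' Per-locus diversity statistics
#'
#' @param x an [SSRGenotypeTable-class].
#' @param loci loci to evaluate (default all).
#' @param corrected small-sample correction for He, see [expectedHet()].
#' @return data frame with one row per locus: locus, nAlleles, nTyped,
#'   He, Ho, PIC, polymorphic.
#' @export
locusStats <- function(x, loci = locusNames(x), corrected = FALSE) {
  rows <- lapply(loci, function(l) {
    p <- alleleFrequencies(x, l)
    nTyped <- sum(!is.na(alleleCalls(x, l)[, 1]))
    data.frame(locus = l,
               nAlleles = length(p),
               nTyped = nTyped,
               He = expectedHet(p, corrected = corrected, n = nTyped),
               Ho = observedHet(x, l),
               PIC = pic(p),
               polymorphic = length(p) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study-level summary of SSR diversity
#'
#' Totals and means over loci of the per-locus statistics. Monomorphic loci
#' are excluded by default, matching the usual practice of reporting genetic
#' statistics for polymorphic markers only.
#'
#' @param stats data frame as returned by [locusStats()] (columns locus,
#'   nAlleles, He, Ho, PIC; a logical \code{polymorphic} column is derived
#'   from \code{nAlleles} when absent).
#' @param polymorphicOnly drop monomorphic loci before summarising.
#' @return one-row data frame: nLoci, totalAlleles, meanAlleles, meanHe,
#'   meanHo, meanPIC.
#' @export
summarizeLoci <- function(stats, polymorphicOnly = TRUE) {
  need <- c("locus", "nAlleles", "He", "Ho", "PIC")
  if (!all(need %in% names(stats)))
    stop("need columns: ", paste(need, collapse = ", "))
  if (!nrow(stats)) stop("empty locus table")
  if (!"polymorphic" %in% names(stats))
    stats$polymorphic <- stats$nAlleles > 1L
  if (polymorphicOnly) stats <- stats[stats$polymorphic, , drop = FALSE]
  if (!nrow(stats)) stop("no polymorphic loci to summarise")
  data.frame(nLoci = nrow(stats),
             totalAlleles = sum(stats$nAlleles),
             meanAlleles = mean(stats$nAlleles),
             meanHe = mean(stats$He),
             meanHo = mean(stats$Ho),
             meanPIC = mean(stats$PIC))
}
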