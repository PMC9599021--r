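#' Euclidean distance over biochemical genotype means
#'
#' Pairwise Euclidean distance between genotypes in the space of assay
#' means. Variables are z-scored by default: the assays live on very
#' different scales (total phenolics in the hundreds of mg/100 g,
#' anthocyanins in the tens), and an unstandardized distance would be
#' dominated by the largest-scaled variable.
#'
#' @param means data frame with a \code{genotype} column (or rownames) and
#'   one numeric column per variable.
#' @param variables columns to use; default all numeric columns.
#' @param standardize z-score each variable first (default TRUE).
#' @return a [stats::dist] object labelled by genotype.
#' @export
biochemDistance <- function(means, variables = NULL, standardize = TRUE) {
  if ("genotype" %in% names(means)) {
    labels <- as.character(means$genotype)
  } else {
    labels <- rownames(means)
  }
  if (is.null(variables))
    variables <- names(means)[vapply(means, is.numeric, logical(1))]
  m <- as.matrix(means[, variables, drop = FALSE])
  rownames(m) <- labels
  if (nrow(m) < 2L) stop("at least 2 genotypes are required")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing value(s): ",
         paste(sprintf("%s/%s", labels[bad[, 1]], variables[bad[, 2]]),
               collapse = ", "))
  }
  if (standardize) m <- scale(m)
  dist(m)
}

#' Genetic distance between diploid SSR genotypes
#'
#' Two metrics over allele fragment sizes:
#' \describe{
#'   \item{\code{allele_size_euclidean}}{each genotype is encoded per locus
#'     as its two allele sizes sorted ascending (or, with
#'     \code{encoding = "mean"}, the per-locus mean size); the distance is
#'     Euclidean over the concatenated vectors. Pairs with missing loci use
#'     the loci typed in both, rescaled by \eqn{\sqrt{L/L_{used}}} so
#'     distances stay on the full-panel scale.}
#'   \item{\code{shared_allele}}{\eqn{D = 1 - } (mean over shared-typed loci
#'     of the number of alleles shared between the two calls, counted as
#'     multisets, divided by 2).}
#' }
#'
#' @param x an [SSRGenotypeTable-class].
#' @param method distance metric.
#' @param encoding for \code{allele_size_euclidean}: \code{"pair"} (sorted
#'   two-size vector, default) or \code{"mean"} (per-locus mean size).
#' @return a [stats::dist] object labelled by genotype.
#' @export
geneticDistance <- function(x,
                            method = c("allele_size_euclidean", "shared_allele"),
                            encoding = c("pair", "mean")) {
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  stopifnot(is(x, "SSRGenotypeTable"))
  n <- nGenotypes(x)
  if (n < 2L) stop("at least 2 genotypes are required")
  L <- nLoci(x)
  lo <- pmin(x@a1, x@a2)
  hi <- pmax(x@a1, x@a2)
  typed <- !is.na(lo)
  d <- matrix(0, n, n, dimnames = list(genotypeNames(x), genotypeNames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- typed[i, ] & typed[j, ]
    if (!any(use))
      stop("genotypes ", genotypeNames(x)[i], " and ", genotypeNames(x)[j],
           " share no typed locus")
    if (method == "allele_size_euclidean") {
      if (encoding == "pair") {
        ss <- sum((lo[i, use] - lo[j, use])^2 + (hi[i, use] - hi[j, use])^2)
      } else {
        mi <- (lo[i, use] + hi[i, use]) / 2
        mj <- (lo[j, use] + hi[j, use]) / 2
        ss <- sum((mi - mj)^2)
      }
      d[i, j] <- d[j, i] <- sqrt(ss * L / sum(use))
    } else {
      shared <- vapply(which(use), function(l) {
        a <- c(lo[i, l], hi[i, l]); b <- c(lo[j, l], hi[j, l])
        # multiset intersection size of two allele pairs
        s <- 0L
        for (al in a) {
          hit <- match(al, b)
          if (!is.na(hit)) { s <- s + 1L; b <- b[-hit] }
        }
        s
      }, integer(1))
      d[i, j] <- d[j, i] <- 1 - mean(shared / 2)
    }
  }
  as.dist(d)
}
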