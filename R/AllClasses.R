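#' Calibration curve for a colorimetric assay
#'
#' A fitted straight line relating absorbance to the concentration of a
#' reference standard (gallic acid, rutin or Trolox). For the ABTS assay the
#' "absorbance" axis is percent inhibition of the blank, which is linear in
#' Trolox concentration over the working range.
#'
#' @slot standard name of the reference standard.
#' @slot slope absorbance units per concentration unit (> 0 for a usable curve).
#' @slot intercept absorbance at zero concentration.
#' @slot range concentration range \code{c(low, high)} spanned by the
#'   standards; inverse predictions outside it are flagged as extrapolation.
#' @slot r.squared coefficient of determination of the fit.
#' @slot n number of standard points used.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(
    standard = "character",
    slope = "numeric",
    intercept = "numeric",
    range = "numeric",
    r.squared = "numeric",
    n = "integer"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope))
    msg <- c(msg, "'slope' must be a single finite number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "'intercept' must be a single finite number")
  if (length(object@range) != 2L || object@range[1] > object@range[2])
    msg <- c(msg, "'range' must be c(low, high) with low <= high")
  if (length(object@r.squared) != 1L ||
      object@r.squared < -1e-8 || object@r.squared > 1 + 1e-8)
    msg <- c(msg, "'r.squared' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve (", object@standard, ")\n", sep = "")
  cat(sprintf("  signal = %.6g * conc + %.6g   (n = %d, r^2 = %.4f)\n",
              object@slope, object@intercept, object@n, object@r.squared))
  cat(sprintf("  calibrated range: %.4g - %.4g\n",
              object@range[1], object@range[2]))
})

#' Diploid SSR genotype table
#'
#' Genotypes x loci table of diploid microsatellite calls. Each call is a
#' pair of allele fragment sizes in base pairs; a call is either fully
#' present or fully missing (both sizes \code{NA}).
#'
#' @slot a1,a2 integer matrices (genotypes x loci) holding the two allele
#'   sizes of every call; \code{a1 <= a2} is not required on input but calls
#'   are stored unordered.
#' @exportClass SSRGenotypeTable
setClass("SSRGenotypeTable",
  representation(a1 = "matrix", a2 = "matrix")
)

setValidity("SSRGenotypeTable", function(object) {
  a1 <- object@a1; a2 <- object@a2
  msg <- character()
  if (!identical(dim(a1), dim(a2)))
    msg <- c(msg, "'a1' and 'a2' must have identical dimensions")
  if (is.null(rownames(a1)) || is.null(colnames(a1)))
    msg <- c(msg, "genotype (row) and locus (column) names are required")
  if (anyDuplicated(rownames(a1)))
    msg <- c(msg, "duplicated genotype names")
  if (anyDuplicated(colnames(a1)))
    msg <- c(msg, "duplicated locus names")
  bad <- function(m) any(!is.na(m) & (m <= 0 | m != round(m)))
  if (bad(a1) || bad(a2))
    msg <- c(msg, "allele sizes must be positive integers (bp)")
  if (!identical(is.na(a1), is.na(a2)))
    msg <- c(msg, "half-missing calls: a call must be fully present or fully missing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SSRGenotypeTable", function(object) {
  cat("SSRGenotypeTable:", nrow(object@a1), "genotypes x",
      ncol(object@a1), "loci\n")
  miss <- sum(is.na(object@a1))
  cat("  missing calls:", miss, "/", length(object@a1), "\n")
  cat("  loci:", paste(head(colnames(object@a1), 8), collapse = ", "),
      if (ncol(object@a1) > 8) "..." else "", "\n")
})

#' Result of Duncan's multiple range test
#'
#' @slot means group means sorted in descending order (named).
#' @slot letters compact-letter display, one string per group, aligned with
#'   \code{means}; groups sharing any letter do not differ at level
#'   \code{alpha}.
#' @slot mse within-group mean square from the one-way ANOVA.
#' @slot dfError error degrees of freedom.
#' @slot n harmonic mean of the group sizes.
#' @slot alpha nominal significance level.
#' @slot criticalRanges least significant range for each span p = 2..k,
#'   using Duncan's protection levels 1 - (1 - alpha)^(p - 1).
#' @slot significant logical matrix over the sorted groups; \code{TRUE} where
#'   the stepwise procedure declares a pair different.
#' @exportClass DuncanResult
setClass("DuncanResult",
  representation(
    means = "numeric",
    letters = "character",
    mse = "numeric",
    dfError = "numeric",
    n = "numeric",
    alpha = "numeric",
    criticalRanges = "numeric",
    significant = "matrix"
  )
)

setMethod("show", "DuncanResult", function(object) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df error = %g, MSE = %.4g)\n",
              object@alpha, object@dfError, object@mse))
  print(data.frame(mean = round(object@means, 4),
                   group = object@letters))
})

#' Result of a Mantel permutation test
#'
#' @slot r Pearson correlation of the off-diagonal entries of the two
#'   distance matrices.
#' @slot pValue one-sided (upper tail) permutation p-value with the +1
#'   correction.
#' @slot nPerm number of permutations.
#' @slot n number of objects (matrix dimension).
#' @slot seed RNG seed used, or \code{NA} if none was supplied.
#' @exportClass MantelResult
setClass("MantelResult",
  representation(
    r = "numeric",
    pValue = "numeric",
    nPerm = "integer",
    n = "integer",
    seed = "integer"
  )
)

setMethod("show", "MantelResult", function(object) {
  cat("Mantel test:", object@n, "objects,", object@nPerm, "permutations\n")
  cat(sprintf("  r = %.4f, one-sided p = %.4g\n", object@r, object@pValue))
})

# ---- plain accessors (Bioconductor convention: no direct slot access) ----

#' @rdname SSRGenotypeTable-class
#' @param x an \code{SSRGenotypeTable}.
#' @export
genotypeNames <- function(x) {
  stopifnot(is(x, "SSRGenotypeTable"))
  rownames(x@a1)
}

#' @rdname SSRGenotypeTable-class
#' @export
locusNames <- function(x) {
  stopifnot(is(x, "SSRGenotypeTable"))
  colnames(x@a1)
}

#' @rdname SSRGenotypeTable-class
#' @export
nGenotypes <- function(x) {
  stopifnot(is(x, "SSRGenotypeTable"))
  nrow(x@a1)
}

#' @rdname SSRGenotypeTable-class
#' @export
nLoci <- function(x) {
  stopifnot(is(x, "SSRGenotypeTable"))
  ncol(x@a1)
}

#' @rdname SSRGenotypeTable-class
#' @param locus locus name or index.
#' @export
alleleCalls <- function(x, locus) {
  stopifnot(is(x, "SSRGenotypeTable"))
  cbind(a1 = x@a1[, locus], a2 = x@a2[, locus])
}
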