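#' Packaged berry assay means
#'
#' Published genotype-level means and standard errors (n = 3 replicates)
#' of the five berry assays for the 25-genotype raspberry germplasm panel
#' (24 raspberry cultivars and breeding lines plus the raspberry x
#' blackberry hybrid Silvan). These means drive the synthetic-data
#' generator's truth table and the reference analyses.
#'
#' @return data frame: genotype, fruit_color, then mean and SE columns for
#'   TPC (mg GAE/100 g FW), TFC (mg RE/100 g FW), TAC (mg cyan-3-G/100 g
#'   FW), FRAP and ABTS (umol TE/g FW).
#' @export
berryAssayMeans <- function() {
  path <- system.file("extdata", "berry_assay_means.csv", package = "phenodiv",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Packaged SSR locus statistics
#'
#' Published per-locus diversity statistics (allele count, He, Ho, PIC) for
#' the seven polymorphic SSR markers from flavonoid biosynthesis genes
#' scored on the 24 diploid red raspberry genotypes of the panel.
#'
#' @return data frame: locus, nAlleles, He, Ho, PIC.
#' @export
ssrLocusStats <- function() {
  path <- system.file("extdata", "ssr_locus_stats.csv", package = "phenodiv",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
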