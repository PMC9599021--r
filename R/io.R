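#' Read a diploid SSR genotype table from CSV
#'
#' Expects the common two-column-per-locus layout: a \code{genotype} column
#' followed by paired columns \code{LOCUS.a1}, \code{LOCUS.a2} (separator
#' \code{.} or \code{_}). A blank, \code{NA} or \code{0} entry marks a
#' missing allele; a call must be missing on both columns or on neither.
#'
#' @param path CSV file path (UTF-8, comma separated, header row).
#' @return an [SSRGenotypeTable-class].
#' @export
readGenotypeTable <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (!"genotype" %in% names(raw))
    stop("missing 'genotype' column in ", path)
  acols <- setdiff(names(raw), "genotype")
  if (length(acols) == 0 || length(acols) %% 2 != 0)
    stop("expected an even number of allele columns (LOCUS.a1/LOCUS.a2), got ",
         length(acols))
  prefix <- sub("[._]a?[12]$", "", acols)
  loci <- unique(prefix)
  if (length(loci) != length(acols) / 2)
    stop("allele columns do not pair up into loci: ",
         paste(acols, collapse = ", "))
  parse_col <- function(colname) {
    v <- raw[[colname]]
    v[v %in% c("", "0", 0, "NA")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num != round(num) | num <= 0))
    if (length(bad))
      stop("non-integer allele size in column '", colname, "', data row(s) ",
           paste(bad, collapse = ", "))
    as.integer(num)
  }
  a1 <- sapply(loci, function(l) parse_col(acols[prefix == l][1]))
  a2 <- sapply(loci, function(l) parse_col(acols[prefix == l][2]))
  if (nrow(raw) == 1L) { a1 <- t(a1); a2 <- t(a2) }
  dimnames(a1) <- dimnames(a2) <- list(as.character(raw$genotype), loci)
  half <- which(is.na(a1) != is.na(a2), arr.ind = TRUE)
  if (nrow(half))
    stop("half-missing call(s): ",
         paste(sprintf("%s/%s", rownames(a1)[half[, 1]], loci[half[, 2]]),
               collapse = ", "))
  SSRGenotypeTable(a1, a2)
}

#' Write an SSR genotype table to CSV
#'
#' Inverse of [readGenotypeTable()]; missing calls are written as 0.
#'
#' @param x an [SSRGenotypeTable-class].
#' @param path output CSV path.
#' @export
writeGenotypeTable <- function(x, path) {
  stopifnot(is(x, "SSRGenotypeTable"))
  out <- data.frame(genotype = genotypeNames(x), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (l in locusNames(x)) {
    calls <- alleleCalls(x, l)
    calls[is.na(calls)] <- 0L
    out[[paste0(l, ".a1")]] <- calls[, 1]
    out[[paste0(l, ".a2")]] <- calls[, 2]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read an absorbance table
#'
#' @param path CSV with columns genotype, assay, replicate, reading_name,
#'   value and optionally dilution_factor.
#' @return validated data frame.
#' @export
readAbsorbanceTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genotype", "assay", "replicate", "reading_name", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!d$assay %in% c("TPC", "TFC", "TAC", "FRAP", "ABTS")))
    stop("unknown assay value(s) in ", path)
  if (any(!is.finite(d$value)) || any(d$value < 0))
    stop("absorbance values must be finite and >= 0")
  d
}

#' Read an extraction-context table
#'
#' @param path CSV with columns genotype, sample_mass_g, extract_volume_ml
#'   and optionally tissue and dry_matter_fraction.
#' @return validated data frame.
#' @export
readContextTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genotype", "sample_mass_g", "extract_volume_ml")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$sample_mass_g <= 0) || any(d$extract_volume_ml <= 0))
    stop("sample mass and extract volume must be > 0")
  if ("dry_matter_fraction" %in% names(d) &&
      any(!is.na(d$dry_matter_fraction) &
          (d$dry_matter_fraction <= 0 | d$dry_matter_fraction >= 1)))
    stop("dry_matter_fraction must lie strictly inside (0, 1)")
  d
}

# reshape a replicate summary into a genotype x variable means table
.meansWide <- function(summary) {
  vars <- unique(summary$variable)
  gs <- unique(summary$genotype)
  m <- matrix(NA_real_, length(gs), length(vars),
              dimnames = list(gs, vars))
  m[cbind(summary$genotype, summary$variable)] <- summary$mean
  data.frame(genotype = gs, m, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full two-domain pipeline
#'
#' Quantify absorbance -> genotype statistics (means, SE, Duncan letters,
#' correlations, fold ranges, grand means) -> SSR diversity -> distance
#' matrices -> UPGMA dendrogram -> Mantel test. Any stage failure aborts
#' with the stage name and cause. When \code{outDir} is given, the standard
#' output files are written (\code{quantified.csv}, \code{summary.csv},
#' \code{correlations.csv}, \code{locus_stats.csv}, \code{clusters.csv},
#' \code{dendrogram.nwk}, \code{mantel.json}, \code{report.json}).
#'
#' @param absorbance absorbance table (see [quantifyAssays()]) or path.
#' @param context context table or path.
#' @param genotypes an [SSRGenotypeTable-class] or path to its CSV.
#' @param outDir optional output directory.
#' @param alpha significance level for Duncan's test.
#' @param standardize z-score biochemical variables before the Euclidean
#'   distance.
#' @param polymorphicOnly restrict locus summaries to polymorphic loci.
#' @param distanceMethod genetic distance metric, see [geneticDistance()].
#' @param k number of clusters to cut from the dendrogram (default 5).
#' @param nPerm Mantel permutations.
#' @param seed seed for the Mantel permutations (recorded in the report).
#' @param curves,dilutionFactors passed to [quantifyAssays()].
#' @return (invisibly) list with elements quantified, summary, means,
#'   correlations, duncan, locusStats, lociSummary, biochemDist,
#'   geneticDist, tree, clusters, mantel, report.
#' @export
runPipeline <- function(absorbance, context, genotypes, outDir = NULL,
                        alpha = 0.05, standardize = TRUE,
                        polymorphicOnly = TRUE,
                        distanceMethod = "shared_allele", k = 5,
                        nPerm = 999, seed = 1,
                        curves = defaultCurves(),
                        dilutionFactors = defaultDilutionFactors()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(absorbance)) absorbance <- readAbsorbanceTable(absorbance)
  if (is.character(context)) context <- readContextTable(context)
  if (is.character(genotypes)) genotypes <- readGenotypeTable(genotypes)

  quant <- stage("quantify",
                 quantifyAssays(absorbance, context, curves, dilutionFactors))
  reps <- data.frame(genotype = quant$genotype, variable = quant$assay,
                     value = quant$value, stringsAsFactors = FALSE)
  summ <- stage("summarize", summarizeGroups(reps))
  duncan <- stage("duncan", {
    res <- lapply(split(reps, reps$variable), function(d)
      duncanTest(d$value, d$genotype, alpha = alpha))
    res
  })
  summ$letters <- vapply(seq_len(nrow(summ)), function(i) {
    dl <- duncan[[summ$variable[i]]]
    unname(dl@letters[summ$genotype[i]])
  }, character(1))
  means <- .meansWide(summ)
  correlations <- stage("correlations", pearsonMatrix(means))
  lstats <- stage("ssr", locusStats(genotypes))
  lsumm <- summarizeLoci(lstats, polymorphicOnly = polymorphicOnly)

  shared <- intersect(means$genotype, genotypeNames(genotypes))
  if (length(shared) < 4)
    stop("pipeline stage 'distance' failed: fewer than 4 genotypes shared ",
         "between the assay and SSR tables", call. = FALSE)
  bd <- stage("distance",
              biochemDistance(means[means$genotype %in% shared, ],
                              standardize = standardize))
  gd <- stage("distance", geneticDistance(genotypes, method = distanceMethod))
  gd <- as.dist(as.matrix(gd)[shared, shared])
  tree <- stage("upgma", upgmaTree(gd))
  clusters <- cutClusters(tree, k = min(k, length(shared)))
  mant <- stage("mantel", mantelTest(bd, gd, nPerm = nPerm, seed = seed))

  report <- list(
    package_version = as.character(utils::packageVersion("phenodiv")),
    seed = seed, alpha = alpha, standardize = standardize,
    polymorphic_only = polymorphicOnly, distance_method = distanceMethod,
    n_genotypes_assay = length(unique(quant$genotype)),
    n_genotypes_ssr = nGenotypes(genotypes),
    fold_range = list(TPC = rangeRatio(means$TPC), TFC = rangeRatio(means$TFC)),
    grand_mean = list(FRAP = grandMean(means$FRAP), ABTS = grandMean(means$ABTS)),
    loci_summary = as.list(lsumm),
    mantel = list(r = mant@r, p = mant@pValue, n_permutations = mant@nPerm)
  )

  out <- list(quantified = quant, summary = summ, means = means,
              correlations = correlations, duncan = duncan,
              locusStats = lstats, lociSummary = lsumm,
              biochemDist = bd, geneticDist = gd, tree = tree,
              clusters = clusters, mantel = mant, report = report)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(quant, file.path(outDir, "quantified.csv"), row.names = FALSE)
    write.csv(summ, file.path(outDir, "summary.csv"), row.names = FALSE)
    write.csv(as.data.frame(correlations),
              file.path(outDir, "correlations.csv"))
    write.csv(lstats, file.path(outDir, "locus_stats.csv"), row.names = FALSE)
    write.csv(data.frame(genotype = names(clusters), cluster = clusters),
              file.path(outDir, "clusters.csv"), row.names = FALSE)
    writeNewick(tree, file.path(outDir, "dendrogram.nwk"))
    jsonlite::write_json(report$mantel, file.path(outDir, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
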