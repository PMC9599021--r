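#' Per-genotype mean and standard error
#'
#' @param replicates long data frame with columns \code{genotype},
#'   \code{variable} (assay name) and \code{value}; one row per replicate.
#' @return data frame genotype, variable, n, mean, se (SE = sd/sqrt(n);
#'   \code{NA} when n = 1).
#' @export
summarizeGroups <- function(replicates) {
  need <- c("genotype", "variable", "value")
  if (!all(need %in% names(replicates)))
    stop("need columns: ", paste(need, collapse = ", "))
  key <- interaction(replicates$genotype, replicates$variable, drop = TRUE)
  out <- lapply(split(replicates, key), function(d) {
    n <- sum(is.finite(d$value))
    v <- d$value[is.finite(d$value)]
    data.frame(genotype = as.character(d$genotype[1L]),
               variable = as.character(d$variable[1L]),
               n = n, mean = mean(v),
               se = if (n > 1) sd(v) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$variable, out$genotype), ]
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition fitted through [stats::lm()].
#'
#' @param values numeric response vector.
#' @param groups group labels, same length (>= 2 groups, each n >= 2).
#' @return list with elements \code{F}, \code{dfBetween}, \code{dfWithin},
#'   \code{ssBetween}, \code{ssWithin}, \code{mse}, \code{p}.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2 replicates")
  tab <- anova(lm(values ~ groups))
  list(F = tab[1, "F value"],
       dfBetween = tab[1, "Df"], dfWithin = tab[2, "Df"],
       ssBetween = tab[1, "Sum Sq"], ssWithin = tab[2, "Sum Sq"],
       mse = tab[2, "Mean Sq"], p = tab[1, "Pr(>F)"])
}

#' Pearson correlation matrix over genotype means
#'
#' @param means data frame (or matrix) of genotype rows by variable columns;
#'   non-selected columns are ignored.
#' @param variables which columns to correlate; default all numeric columns.
#' @return symmetric matrix of Pearson r with unit diagonal; a variable with
#'   zero variance yields \code{NA} entries with a warning. Attribute
#'   \code{"n"} carries the pairwise complete sample sizes.
#' @export
pearsonMatrix <- function(means, variables = NULL) {
  if (is.null(variables))
    variables <- names(means)[vapply(means, is.numeric, logical(1))]
  m <- as.matrix(means[, variables, drop = FALSE])
  if (nrow(m) < 3L) stop("at least 3 genotypes are required")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero variance in: ",
            paste(variables[which(sds == 0)], collapse = ", "),
            " (correlations reported as NA)")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- ifelse(is.finite(diag(r)), 1, NA_real_)
  nmat <- crossprod(!is.na(m))
  attr(r, "n") <- nmat
  r
}

#' Fold range (max/min) of a positive vector
#'
#' @param x numeric vector, all values > 0.
#' @return \code{max(x)/min(x)}.
#' @export
rangeRatio <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty input")
  if (min(x) <= 0) stop("fold range requires strictly positive values")
  max(x) / min(x)
}

#' Grand mean over genotypes
#'
#' @param x numeric vector of genotype means.
#' @return arithmetic mean.
#' @export
grandMean <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty input")
  mean(x)
}
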