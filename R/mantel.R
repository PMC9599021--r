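#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries of two distance matrices
#' over the same objects, with significance assessed by jointly permuting
#' the rows and columns of the second matrix. The matrices are aligned by
#' label, not by position. The p-value is one-sided (upper tail) with the
#' +1 correction: \eqn{p = (1 + \#\{r^* \ge r\}) / (B + 1)}.
#'
#' @param d1,d2 [stats::dist] objects (or symmetric matrices) with matching
#'   label sets, n >= 4.
#' @param nPerm number of permutations (default 9999).
#' @param seed optional integer seed for reproducible permutations; the
#'   caller's RNG state is preserved.
#' @return a [MantelResult-class] object.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(30), 15)
#' mantelTest(dist(x), dist(x + rnorm(30, sd = 2)), nPerm = 99)
#' @export
mantelTest <- function(d1, d2, nPerm = 9999, seed = NULL) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (is.null(l1) || is.null(l2))
    stop("both matrices must carry labels for alignment")
  if (!setequal(l1, l2))
    stop("label mismatch between the two matrices")
  m2 <- m2[l1, l1]
  n <- nrow(m1)
  if (n < 4L) stop("at least 4 objects are required")
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (sd(v1) == 0 || sd(m2[ut]) == 0)
    stop("zero variance in the off-diagonal entries of a matrix")

  r <- cor(v1, m2[ut])

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(list = ".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(n)
    rstar <- cor(v1, m2[idx, idx][ut])
    if (rstar >= r) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (nPerm + 1)

  new("MantelResult", r = r, pValue = p, nPerm = as.integer(nPerm),
      n = as.integer(n),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
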