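#' Duncan's multiple range test with compact-letter display
#'
#' Classical Duncan MRT after a one-way ANOVA. Group means are ranked;
#' a range spanning p ordered means is tested against the least significant
#' range \eqn{R_p = q(\alpha_p, p, df_e)\sqrt{MSE/n}} where
#' \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}} is Duncan's protection level and q
#' the studentized range quantile. The step-down rule applies: a range
#' contained in a non-significant range is itself declared non-significant
#' without testing. Letters are assigned by the insert-and-absorb algorithm,
#' so groups sharing a letter do not differ at level \code{alpha}.
#'
#' With unequal group sizes the harmonic mean of the n's is used (with a
#' warning), following the classical definition; the study design this
#' implements is balanced at n = 3.
#'
#' @param values numeric response vector (replicate observations).
#' @param groups group labels, same length.
#' @param alpha nominal significance level (default 0.05).
#' @return a [DuncanResult-class] object.
#' @examples
#' set.seed(1)
#' y <- c(rnorm(3, 10), rnorm(3, 10.2), rnorm(3, 30))
#' g <- rep(c("A", "B", "C"), each = 3)
#' duncanTest(y, g)
#' @export
duncanTest <- function(values, groups, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  groups <- factor(groups)
  av <- oneWayAnova(values, groups)
  ns <- tapply(values, groups, function(v) sum(is.finite(v)))
  if (length(unique(ns)) > 1L)
    warning("unequal group sizes: using the harmonic mean of n")
  nh <- length(ns) / sum(1 / ns)
  m <- tapply(values, groups, mean, na.rm = TRUE)
  m <- setNames(as.numeric(m), names(m))
  # descending means; ties keep input (factor level) order
  ord <- order(-m)
  m <- m[ord]
  k <- length(m)

  spans <- 2:k
  alphap <- 1 - (1 - alpha)^(spans - 1)
  q <- mapply(.qtukeySafe, 1 - alphap, spans,
              MoreArgs = list(df = av$dfWithin))
  Rp <- q * sqrt(av$mse / nh)
  names(Rp) <- spans

  # step-down testing over ranked means
  sig <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  nonsigRange <- list()  # closed intervals [a, b] declared non-significant
  covered <- function(i, j) {
    for (iv in nonsigRange) if (iv[1] <= i && j <= iv[2]) return(TRUE)
    FALSE
  }
  if (k >= 2) {
    for (p in k:2) {
      for (i in seq_len(k - p + 1)) {
        j <- i + p - 1
        if (covered(i, j)) next
        if (m[i] - m[j] > Rp[as.character(p)]) {
          sig[i, j] <- sig[j, i] <- TRUE
        } else {
          nonsigRange[[length(nonsigRange) + 1L]] <- c(i, j)
        }
      }
    }
  }

  letters <- .insertAbsorb(sig)
  new("DuncanResult",
      means = m, letters = letters,
      mse = av$mse, dfError = av$dfWithin, n = nh, alpha = alpha,
      criticalRanges = Rp, significant = sig)
}

# Studentized-range quantile with a numeric fallback: qtukey can fail to
# converge for low probabilities at large group counts; invert ptukey then.
.qtukeySafe <- function(prob, nmeans, df) {
  q <- suppressWarnings(qtukey(prob, nmeans, df))
  if (!is.finite(q)) {
    q <- uniroot(function(x) stats::ptukey(x, nmeans, df) - prob,
                 lower = 1e-6, upper = 500, tol = 1e-9)$root
  }
  q
}

# Compact-letter display by insert-and-absorb. `sig` is the symmetric logical
# significance matrix over groups already sorted by descending mean. Returns
# one letter-string per group, in the same order.
.insertAbsorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      newcols <- list()
      for (cl in cols) {
        if (i %in% cl && j %in% cl) {
          newcols <- c(newcols, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          newcols <- c(newcols, list(cl))
        }
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            !(all(newcols[[b]] %in% newcols[[a]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
      cols <- newcols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  symbols <- c(letters, as.vector(outer(letters, letters, paste0)))
  out <- vapply(seq_len(k), function(g) {
    paste0(symbols[which(vapply(cols, function(cl) g %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  names(out) <- rownames(sig)
  out
}
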