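#' UPGMA (average linkage) dendrogram
#'
#' Agglomerative clustering with unweighted arithmetic averaging of
#' between-cluster distances. Node heights are half the merge distance, so
#' the tree is ultrametric and the cophenetic distance between two leaves
#' equals the distance at which their clusters merged. Ties in the minimum
#' inter-cluster distance are broken deterministically by the smallest leaf
#' index contained in each candidate cluster, giving bit-reproducible
#' output.
#'
#' @param d a [stats::dist] object (or symmetric matrix with zero diagonal)
#'   over >= 2 labelled objects; \code{NA}/\code{NaN} entries are an error.
#' @return an object of class \code{c("upgma", "hclust")}; heights are merge
#'   distance / 2. Use [cutClusters()], [copheneticDistance()],
#'   [writeNewick()] or \code{ape::as.phylo()} on it.
#' @examples
#' d <- dist(c(A = 0, B = 2, C = 6))
#' plot(upgmaTree(d))
#' @export
upgmaTree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2L) stop("at least 2 objects are required")
  if (any(is.na(m))) stop("NA/NaN entries in the distance matrix")
  if (any(m < 0)) stop("negative distances")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)

  # active clusters: member leaf indices, hclust id (-leaf or +merge row)
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  active <- rep(TRUE, n + n - 1)
  D <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
  D[1:n, 1:n] <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  cur <- n
  alive <- seq_len(n)

  for (step in seq_len(n - 1)) {
    best <- NULL
    bestd <- Inf
    for (ai in seq_along(alive)) {
      for (aj in seq_along(alive)) {
        if (aj <= ai) next
        i <- alive[ai]; j <- alive[aj]
        dij <- D[i, j]
        if (dij < bestd - 1e-12) {
          bestd <- dij; best <- c(i, j)
        } else if (abs(dij - bestd) <= 1e-12) {
          # tie: smallest contained leaf index, then smallest partner
          key <- sort(c(min(members[[i]]), min(members[[j]])))
          bkey <- sort(c(min(members[[best[1]]]), min(members[[best[2]]])))
          if (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    cur <- cur + 1
    new_id <- cur
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- bestd / 2
    members[[new_id]] <- sort(c(members[[i]], members[[j]]))
    sizes[new_id] <- sizes[i] + sizes[j]
    # unweighted average linkage update
    for (k in alive) {
      if (k == i || k == j) next
      D[new_id, k] <- D[k, new_id] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    ids[new_id] <- step
    alive <- c(setdiff(alive, c(i, j)), new_id)
  }

  ordr <- integer(0)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  ordr <- walk(n - 1)

  structure(list(merge = merge, height = height, order = ordr,
                 labels = labels, method = "upgma",
                 call = match.call(), dist.method = attr(d, "method")),
            class = c("upgma", "hclust"))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges, assigning every leaf to exactly one
#' cluster. Alternatively cut at a height (on the merge-distance/2 scale).
#'
#' @param tree an \code{hclust}-like tree from [upgmaTree()].
#' @param k desired number of clusters (1..n leaves), or
#' @param h height at which to cut (used when \code{k} is NULL).
#' @return named integer vector of cluster memberships.
#' @export
cutClusters <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (is.null(k) && is.null(h)) stop("supply 'k' or 'h'")
  if (!is.null(k)) {
    nleaf <- length(tree$labels)
    if (k < 1 || k > nleaf || k != round(k))
      stop("'k' must be an integer in 1..", nleaf)
    cutree(tree, k = k)
  } else {
    cutree(tree, h = h)
  }
}

#' Cophenetic distances of an ultrametric tree
#'
#' For a tree from [upgmaTree()] (heights = merge distance / 2) this is
#' twice the cophenetic height, i.e. the distance at which two leaves were
#' merged — directly comparable with the input distances.
#'
#' @param tree an \code{hclust}-like tree from [upgmaTree()].
#' @return a [stats::dist] object.
#' @export
copheneticDistance <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  2 * cophenetic(tree)
}

#' Write a dendrogram to a Newick file
#'
#' Converts the tree to an \code{ape::phylo} and writes Newick; branch
#' lengths follow the ultrametric node heights, so leaf-to-leaf path length
#' equals the cophenetic distance.
#'
#' Characters that are syntax in Newick (spaces, parentheses, commas,
#' colons, semicolons, quotes) are replaced by underscores in leaf labels.
#'
#' @param tree an \code{hclust}-like tree from [upgmaTree()].
#' @param file output path; with \code{file = ""} the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = "") {
  class(tree) <- "hclust"
  # as.phylo.hclust halves merge heights (it expects full-distance heights);
  # ours are already distance/2, so pre-double to keep node depths at d/2
  tree$height <- tree$height * 2
  phy <- ape::as.phylo(tree)
  phy$tip.label <- gsub("[ (),:;'\"]", "_", phy$tip.label)
  if (identical(file, "")) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}
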