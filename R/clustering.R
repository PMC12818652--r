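#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with complete (maximum) linkage, implemented so
#' that tie-breaking is fully deterministic: among all pairs at the current
#' minimal distance, the pair whose (sorted) smallest member labels are
#' lexicographically smallest is merged first. Merge heights are
#' non-decreasing (complete linkage is monotone). The result is a standard
#' `hclust` object, so it can be cut, plotted, or converted with
#' [stats::cophenetic()] and [ape::as.phylo()].
#'
#' @param dm a symmetric distance matrix with zero diagonal and dimnames
#'   (e.g. from [distance_matrix()]), or a `dist` object.
#' @return an object of class `hclust`.
#' @export
complete_linkage_cluster <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 2L) stop("clustering needs at least 2 items")
  if (max(abs(dm - t(dm))) > 1e-9 || any(diag(dm) != 0) || any(dm < 0))
    stop("dm must be symmetric, non-negative, with zero diagonal")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- dm; diag(D) <- Inf
  node <- -seq_len(n)          # hclust convention: negative = singleton
  minlab <- labels             # smallest member label per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on the pair of smallest member labels
    keys <- apply(cand, 1L, function(rc) {
      paste(sort(c(minlab[idx[rc[1]]], minlab[idx[rc[2]]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]

    a <- node[i]; b <- node[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp }   # negatives (singletons) first
    merge[step, ] <- c(a, b)
    height[step] <- dmin

    newd <- pmax(D[i, ], D[j, ])                # complete linkage
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    node[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
  }

  unpack <- function(k) {
    if (k < 0) return(-k)
    c(unpack(merge[k, 1]), unpack(merge[k, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = unpack(n - 1L), labels = labels,
                 method = "complete", call = match.call(),
                 dist.method = "wasserstein1d"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string or file
#'
#' @param hc an `hclust` object.
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
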