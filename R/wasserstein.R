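#' Exact 1-D p-Wasserstein distance between empirical distributions
#'
#' Computed from the quantile functions: the merged set of cumulative-
#' probability breakpoints of the two empirical CDFs partitions (0, 1] into
#' segments on which both quantile functions are constant, and the distance
#' is the (p-th root of the) probability-weighted sum of
#' `|Q_x(t) - Q_y(t)|^p` over those segments. No binning and no Monte
#' Carlo; for equal sample sizes and p = 1 this reduces to the mean
#' absolute difference of the sorted values.
#'
#' @param x,y non-empty numeric samples.
#' @param p order of the distance (default 1, the W1 used for tissue
#'   comparisons).
#' @return non-negative scalar.
#' @examples
#' wasserstein1d(c(0, 2), c(1, 3))  # 1
#' @export
wasserstein1d <- function(x, y, p = 1) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("wasserstein1d() requires non-empty samples")
  stopifnot(p >= 1)
  x <- sort(x); y <- sort(y)
  n <- length(x); m <- length(y)
  if (n == m) return(mean(abs(x - y)^p)^(1 / p))
  tt <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lower <- c(0, tt[-length(tt)])
  dt <- tt - lower
  # quantile index on the open segment (lower, tt]: floor(lower * n) + 1
  ix <- pmin(n, floor(lower * n + 1e-9) + 1L)
  iy <- pmin(m, floor(lower * m + 1e-9) + 1L)
  sum(dt * abs(x[ix] - y[iy])^p)^(1 / p)
}

#' Pairwise Wasserstein distance matrix between tissue groups
#'
#' Distances are computed on the raw per-sample in-ex ratios of each group
#' (histogram bins are presentation only). Groups are ordered
#' lexicographically for reproducibility.
#'
#' @param cohort a filtered cohort table.
#' @param group_col grouping column (default `"tissue_type"`).
#' @param value_col value column (default `"inex_ratio"`).
#' @param p Wasserstein order (default 1).
#' @return symmetric matrix with zero diagonal, dimnames = group labels.
#' @export
distance_matrix <- function(cohort, group_col = "tissue_type",
                            value_col = "inex_ratio", p = 1) {
  cohort <- data.table::as.data.table(cohort)
  g <- as.character(cohort[[group_col]])
  v <- cohort[[value_col]]
  keep <- is.finite(v)
  g <- g[keep]; v <- v[keep]
  labs <- sort(unique(g))
  if (length(labs) < 2L)
    stop("distance_matrix() needs at least 2 groups with data")
  sets <- split(v, factor(g, levels = labs))
  k <- length(labs)
  dm <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    dm[i, j] <- dm[j, i] <- wasserstein1d(sets[[i]], sets[[j]], p = p)
  }
  dm
}

#' Write a distance matrix as TSV
#'
#' @param dm square matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  dt <- data.table::data.table(tissue = rownames(dm))
  dt <- cbind(dt, data.table::as.data.table(dm))
  write_tsv_prov(dt, path)
}
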