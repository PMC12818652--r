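# Independent oracles used by the property tests. Each re-derives its
# quantity by a different algorithm than the package implementation.

# Exact 1-Wasserstein distance as the solution of the discrete transport
# problem: northwest-corner matching on sorted supports, which is optimal
# for a convex cost in one dimension. Integer masses (m per x-atom, n per
# y-atom over a common denominator n*m) keep the bookkeeping exact.
oracle_w1 <- function(x, y) {
  n <- length(x); m <- length(y)
  x <- sort(x); y <- sort(y)
  wx <- rep(m, n); wy <- rep(n, m)
  i <- 1L; j <- 1L; cost <- 0
  while (i <= n && j <= m) {
    mm <- min(wx[i], wy[j])
    cost <- cost + mm * abs(x[i] - y[j])
    wx[i] <- wx[i] - mm
    wy[j] <- wy[j] - mm
    if (wx[i] == 0L) i <- i + 1L
    if (j <= m && wy[j] == 0L) j <- j + 1L
  }
  cost / (n * m)
}

# Exact two-sided rank-sum p-value by full enumeration of all C(N, n1)
# assignments of the pooled midranks to the first sample.
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  combs <- utils::combn(N, n1)
  Ws <- colSums(matrix(r[combs], nrow = n1))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Independent YCAY-cluster scorer: character-level motif walk plus an
# explicit grouping loop, coded separately from the package's regex-based
# scanner.
oracle_find_motifs <- function(s) {
  s <- chartr("T", "U", toupper(s))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  isY <- ch %in% c("C", "U")
  pos <- integer(0)
  i <- 1L
  while (i <= length(ch) - 3L) {
    if (isY[i] && ch[i + 1L] == "C" && ch[i + 2L] == "A" && isY[i + 3L]) {
      pos <- c(pos, i - 1L)
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  pos
}

oracle_score45 <- function(s) {
  p <- oracle_find_motifs(s)
  k <- length(p)
  if (k < 2L) return(0L)
  total <- 0L
  idx <- 1L
  while (idx <= k - 1L) {
    d1 <- p[idx + 1L] - p[idx] - 4L
    if (d1 >= 7L) { idx <- idx + 1L; next }
    d2 <- if (idx + 2L <= k) p[idx + 2L] - p[idx + 1L] - 4L else NA_integer_
    if (!is.na(d2) && d2 <= 6L) {
      if (d1 <= 2L && d2 <= 2L) { total <- total + 8L; idx <- idx + 3L }
      else if (d1 <= 2L || d2 <= 2L) { total <- total + 4L; idx <- idx + 3L }
      else { total <- total + 1L; idx <- idx + 2L }  # (3-6, 3-6): pair + carry
    } else {
      total <- total + (if (d1 <= 2L) 2L else 1L)
      idx <- idx + 2L
    }
  }
  total
}

# Direct position-by-position running sum for the weighted enrichment
# score (no jump shortcut), returning the extremum of largest magnitude
# with the positive-on-tie rule.
oracle_es <- function(scores, hit, weight_p = 1) {
  N <- length(scores)
  w <- abs(scores)^weight_p
  nr <- sum(w[hit])
  nh <- sum(hit)
  run <- 0
  best_max <- -Inf; best_min <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (nr > 0) w[i] / nr else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    best_max <- max(best_max, run)
    best_min <- min(best_min, run)
  }
  if (abs(best_max) >= abs(best_min)) best_max else best_min
}

# Random 45-mer over the RNA alphabet.
random_45mer <- function() {
  paste(sample(c("A", "C", "G", "U"), 45L, replace = TRUE), collapse = "")
}

# Small synthetic sample table in the per-sample summary layout, two species.
make_sample_table <- function(seed = 7L, n_per_group = 12L) {
  set.seed(seed)
  rows <- list()
  for (sp in c("speciesA", "speciesB")) {
    for (grp in list(list(cat = "forebrain", p = 0.75),
                     list(cat = "liver", p = 0.2))) {
      tot <- rnbinom(n_per_group, size = 10, mu = 60) + 3L
      inc <- rbinom(n_per_group, tot, grp$p)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sample_id = sprintf("%s_%s_%02d", sp, grp$cat, seq_len(n_per_group)),
        species = sp, tissue_type = grp$cat, tissue_category = grp$cat,
        inclusion_reads = inc, exclusion_reads = tot - inc,
        gene_tpm = rgamma(n_per_group, shape = 4, rate = 0.1))
    }
  }
  dt <- data.table::rbindlist(rows)
  dt[, inex_ratio := compute_inex_ratio(inclusion_reads, exclusion_reads)]
  dt[, is_cns := assign_cns(tissue_category)]
  dt[]
}
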