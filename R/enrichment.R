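#' Rank genes by correlation of expression with the in-ex ratio
#'
#' Computes the Pearson correlation between each gene's expression (TPM)
#' and the per-sample in-ex ratio, over the samples shared by both inputs,
#' and returns the genes sorted by correlation, descending. Genes with zero
#' expression variance get score 0 and are flagged rather than dropped.
#' Ties are broken by gene id (lexicographic) so the ranking is
#' reproducible.
#'
#' @param expression numeric matrix, samples in rows (rownames = sample
#'   ids), genes in columns; or a `data.frame` with a `sample_id` column.
#' @param inex named numeric vector of in-ex ratios (names = sample ids).
#' @return a `data.table` with `gene_id`, `score`, `zero_variance`, sorted
#'   by score descending.
#' @export
correlate_genes <- function(expression, inex) {
  if (is.data.frame(expression)) {
    expression <- data.table::as.data.table(expression)
    if (!"sample_id" %in% names(expression))
      stop("expression data.frame needs a 'sample_id' column")
    ids <- expression$sample_id
    expression <- as.matrix(expression[, !"sample_id"])
    rownames(expression) <- ids
  }
  if (is.null(rownames(expression)) || is.null(names(inex)))
    stop("expression rownames and inex names must carry sample ids")
  common <- intersect(rownames(expression), names(inex))
  common <- common[is.finite(inex[common])]
  if (length(common) < 3L)
    stop("need at least 3 overlapping samples with finite in-ex ratio")
  E <- expression[common, , drop = FALSE]
  v <- inex[common]
  sds <- apply(E, 2L, stats::sd)
  score <- rep(0, ncol(E))
  ok <- sds > 0 & stats::sd(v) > 0
  if (any(ok)) score[ok] <- as.vector(cor(v, E[, ok, drop = FALSE]))
  out <- data.table::data.table(gene_id = colnames(E), score = score,
                                zero_variance = !ok)
  data.table::setorder(out, -score, gene_id)
  out[]
}

#' Read and write GMT gene-set collections
#'
#' Tab-separated GMT: set name, description, then member genes. Members are
#' de-duplicated on read; sets left empty are dropped.
#'
#' @param path file path.
#' @return `read_gmt()`: a named list of character vectors with a
#'   `descriptions` attribute; `write_gmt()`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0L]
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "",
                 character(1))
  names(desc) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene-set collection to usable set sizes
#'
#' Keeps the sets whose intersection with the ranked gene universe has size
#' within `[min_size, max_size]`, inclusive on both ends.
#'
#' @param sets named list of gene-id vectors.
#' @param ranked a ranked gene list from [correlate_genes()] (or anything
#'   with a `gene_id` column).
#' @param min_size,max_size inclusive bounds (defaults 20 and 500).
#' @return the filtered list, members restricted to the universe.
#' @export
filter_gene_sets <- function(sets, ranked, min_size = 20L, max_size = 500L) {
  universe <- data.table::as.data.table(ranked)$gene_id
  inter <- lapply(sets, intersect, y = universe)
  keep <- lengths(inter) >= min_size & lengths(inter) <= max_size
  out <- inter[keep]
  attr(out, "descriptions") <- attr(sets, "descriptions")[names(out)]
  out
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-style statistic over a ranked list: the
#' running sum gains `|score|^weight_p / sum(|member scores|^weight_p)` at
#' member positions and loses `1/(N - N_members)` elsewhere; the
#' enrichment score is the extremum of largest magnitude (ties resolved in
#' favour of the positive extremum). With `weight_p = 0` this is the
#' classic KS statistic on ranks.
#'
#' @param ranked ranked gene list ([correlate_genes()] layout), already
#'   sorted by score descending.
#' @param members character vector of member gene ids.
#' @param weight_p score-weighting exponent (default 1).
#' @return a list: `es` and the full `running_sum` vector.
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  ranked <- data.table::as.data.table(ranked)
  hit <- ranked$gene_id %in% members
  if (!any(hit)) stop("no gene-set member present in the ranked list")
  if (all(hit)) stop("gene set spans the whole ranked list")
  w <- abs(ranked$score)^weight_p
  w[!hit] <- 0
  tot <- sum(w)
  inc <- if (tot == 0) hit / sum(hit) else w / tot
  miss <- 1 / (sum(!hit))
  running <- cumsum(inc - (!hit) * miss)
  es_max <- max(running); es_min <- min(running)
  es <- if (abs(es_max) >= abs(es_min)) es_max else es_min
  list(es = es, running_sum = running)
}

# Fast ES from member positions only: between hits the running sum decays
# linearly, so the extrema lie immediately after a hit (maximum candidates)
# or just before one (minimum candidates). O(N_members) per evaluation;
# used for the permutation null.
es_from_positions <- function(absw, pos, N) {
  pos <- sort(pos)
  k <- length(pos)
  w <- absw[pos]
  tot <- sum(w)
  inc <- if (tot == 0) rep(1 / k, k) else w / tot
  miss <- 1 / (N - k)
  cum_inc <- cumsum(inc)
  after <- cum_inc - (pos - seq_len(k)) * miss
  before <- c(0, cum_inc[-k]) - (pos - 1 - (seq_len(k) - 1)) * miss
  es_max <- max(after); es_min <- min(c(before, 0))
  if (abs(es_max) >= abs(es_min)) es_max else es_min
}

#' Pre-ranked gene-set enrichment with gene-label permutations
#'
#' For each set, computes the weighted running-sum enrichment score of
#' [enrichment_score()], then a permutation null by redrawing the member
#' positions uniformly (`n_perm` gene-label permutations under the given
#' seed). NES is ES divided by the mean |ES| of same-sign permutations
#' (the original GSEA normalisation); the empirical p-value is
#' the same-sign tail `(1 + #{same-sign perms with |ES_perm| >= |ES|}) /
#' (1 + #{same-sign perms})`, approximately uniform under the null, with
#' floor `1/(1 + #same-sign perms)` (at best `1/(n_perm + 1)` when every
#' permutation shares the observed sign). Benjamini-Hochberg adjustment is
#' applied across sets and sets with `p_adjusted < p_cutoff` are flagged.
#'
#' @param ranked ranked gene list, sorted by score descending.
#' @param sets gene-set collection (pre-filter with [filter_gene_sets()]).
#' @param weight_p weighting exponent (default 1).
#' @param n_perm number of permutations (default 1000; below 100 a warning
#'   is issued because NES becomes unstable).
#' @param seed integer seed controlling the permutations; the caller's RNG
#'   state is left untouched.
#' @param p_cutoff adjusted-p threshold for the `significant` flag
#'   (default 0.01).
#' @param top_bottom_k optionally truncate the ranked list to its top and
#'   bottom `k` entries before scoring (default `NULL`: full list).
#' @return a `data.table`: `set_name`, `size`, `es`, `nes`, `p_value`,
#'   `p_adjusted`, `significant`, sorted by `p_value`.
#' @export
gsea_preranked <- function(ranked, sets, weight_p = 1, n_perm = 1000L,
                           seed = 1111L, p_cutoff = 0.01,
                           top_bottom_k = NULL) {
  ranked <- data.table::as.data.table(ranked)
  if (!is.null(top_bottom_k)) {
    k <- min(top_bottom_k, ceiling(nrow(ranked) / 2))
    ranked <- unique(rbind(head(ranked, k), tail(ranked, k)),
                     by = "gene_id")
  }
  if (n_perm < 100L) warning("n_perm < 100 gives unstable NES estimates")
  if (!length(sets)) stop("empty gene-set collection")
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight_p
  res <- with_local_seed(seed, {
    out <- vector("list", length(sets))
    for (si in seq_along(sets)) {
      members <- sets[[si]]
      hitpos <- which(ranked$gene_id %in% members)
      if (!length(hitpos)) next
      es <- es_from_positions(absw, hitpos, N)
      k <- length(hitpos)
      perm <- vapply(seq_len(n_perm), function(b) {
        es_from_positions(absw, sample.int(N, k), N)
      }, numeric(1))
      same <- perm[sign(perm) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      out[[si]] <- data.table::data.table(
        set_name = names(sets)[si], size = k, es = es, nes = nes,
        p_value = p)
    }
    data.table::rbindlist(out)
  })
  if (!nrow(res)) stop("no gene set overlaps the ranked list")
  res[, p_adjusted := p.adjust(p_value, method = "BH")]
  res[, significant := p_adjusted < p_cutoff]
  data.table::setorder(res, p_value, set_name)
  res[]
}

#' Write a ranked gene list as TSV
#'
#' @param ranked ranked gene list.
#' @param path file path.
#' @export
write_ranked_list <- function(ranked, path) {
  write_tsv_prov(data.table::as.data.table(ranked), path)
}
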