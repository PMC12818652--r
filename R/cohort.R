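#' Tissue categories treated as central nervous system
#'
#' Default lookup used by [assign_cns()]; matching is case-insensitive on
#' the whole category string. Override by passing your own vector, e.g.
#' when a metadata source uses different category labels.
#'
#' @return character vector of CNS tissue-category names.
#' @export
cns_categories <- function() {
  c("brain", "forebrain", "midbrain", "hindbrain", "cerebellum",
    "spinal cord", "neural tube", "cns")
}

#' Flag CNS samples from their tissue category
#'
#' @param tissue_category character vector of category labels.
#' @param cns categories counted as CNS (default [cns_categories()]).
#' @return logical vector.
#' @export
assign_cns <- function(tissue_category, cns = cns_categories()) {
  tolower(trimws(tissue_category)) %in% tolower(cns)
}

#' Apply the cohort sample filters
#'
#' Retains samples with target-gene expression `gene_tpm >= tpm_min` and a
#' combined junction-read total `inclusion_reads + exclusion_reads >=
#' min_junction_reads`; both thresholds are inclusive. Samples whose ratio
#' is undefined (0 + 0 reads) never pass the read filter. The operation is
#' idempotent.
#'
#' @param records a `data.frame`/`data.table` of sample records with at
#'   least `inclusion_reads`, `exclusion_reads`, `gene_tpm`.
#' @param tpm_min minimum target-gene TPM (default 1).
#' @param min_junction_reads minimum combined junction reads (default 3).
#' @param species_label optional label stored as an attribute.
#' @return the filtered `data.table` with attributes `n_input`,
#'   `n_retained`, `retained_by_tissue` (a table, when `tissue_type` is
#'   present) and `species_label`.
#' @export
filter_samples <- function(records, tpm_min = 1, min_junction_reads = 3,
                           species_label = NA_character_) {
  records <- data.table::as.data.table(records)
  need <- c("inclusion_reads", "exclusion_reads", "gene_tpm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- records$gene_tpm >= tpm_min &
    (records$inclusion_reads + records$exclusion_reads) >= min_junction_reads
  out <- records[keep]
  data.table::setattr(out, "n_input", nrow(records))
  data.table::setattr(out, "n_retained", nrow(out))
  if ("tissue_type" %in% names(out))
    data.table::setattr(out, "retained_by_tissue", table(out$tissue_type))
  data.table::setattr(out, "species_label", species_label)
  out[]
}

#' Per-group histogram summaries of the in-ex ratio
#'
#' Bins the ratios of each group into fixed-width bins spanning `[-1, 1]`
#' and normalises each group's histogram to unit area (density x bin width
#' sums to 1), matching how per-tissue and CNS/other histograms are
#' normalised for display. Groups with no finite ratio are omitted with a
#' warning.
#'
#' @param cohort a filtered cohort table with `inex_ratio` and the grouping
#'   column.
#' @param group_by `"tissue_type"` or `"cns_flag"` (the `is_cns` column).
#' @param bin_width bin width over `[-1, 1]`; must divide 2 evenly
#'   (default 0.1, i.e. 20 bins).
#' @return a `data.table` with `group`, `bin_left`, `bin_right`, `count`,
#'   `density`; attribute `group_sizes`.
#' @export
tissue_distribution <- function(cohort, group_by = c("tissue_type", "cns_flag"),
                                bin_width = 0.1) {
  group_by <- match.arg(group_by)
  cohort <- data.table::as.data.table(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  nbin <- round(2 / bin_width)
  if (abs(nbin * bin_width - 2) > 1e-9)
    stop("bin_width must divide the interval [-1, 1] evenly")
  breaks <- seq(-1, 1, length.out = nbin + 1L)
  g <- if (group_by == "tissue_type") as.character(cohort$tissue_type)
       else ifelse(cohort$is_cns, "CNS", "other")
  res <- list(); sizes <- integer()
  for (grp in sort(unique(g))) {
    x <- cohort$inex_ratio[g == grp]
    x <- x[is.finite(x)]
    if (!length(x)) {
      warning("group '", grp, "' has no finite in-ex ratio; omitted")
      next
    }
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE,
                                  left.open = TRUE), 1L), nbin)
    cnt <- tabulate(idx, nbins = nbin)
    res[[grp]] <- data.table::data.table(
      group = grp, bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
      count = cnt, density = cnt / (length(x) * bin_width))
    sizes[grp] <- length(x)
  }
  if (!length(res)) stop("no group with data")
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "group_sizes", sizes)
  out[]
}

#' Read a sample table in the per-sample summary layout
#'
#' Reads a tab-separated export of a per-sample summary table (one row per
#' RNA-seq sample) with columns `sample_id`, `tissue_type`,
#' `tissue_category`, `inclusion_reads`, `exclusion_reads`, `gene_tpm` and
#' optionally `species`. Adds `inex_ratio` (recomputed from the counts) and
#' `is_cns` (via [assign_cns()]).
#'
#' @param path TSV file path.
#' @param cns CNS category lookup passed to [assign_cns()].
#' @return a `data.table` of sample records.
#' @export
read_sample_table <- function(path, cns = cns_categories()) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "tissue_type", "tissue_category",
            "inclusion_reads", "exclusion_reads", "gene_tpm")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dt[, inex_ratio := compute_inex_ratio(inclusion_reads, exclusion_reads)]
  dt[, is_cns := assign_cns(tissue_category, cns)]
  dt[]
}

#' CNS vs non-CNS effect sizes per species from a per-sample summary table
#'
#' For each species in the table: apply [filter_samples()] with the default
#' thresholds, then test CNS against non-CNS in-ex ratios with
#' [wilcoxon_ranksum()] and report the rank-based effect size r = |Z|/sqrt(N).
#'
#' @param records output of [read_sample_table()] (must contain `species`).
#' @param mode Wilcoxon mode passed through (default `"auto"`).
#' @return a `data.table` with `species`, `n_retained`, `n_tissue_types`,
#'   `p_value`, `z_statistic`, `effect_size_r`.
#' @export
species_effect_sizes <- function(records, mode = "auto") {
  records <- data.table::as.data.table(records)
  if (!"species" %in% names(records)) stop("missing column(s): species")
  out <- list()
  for (sp in unique(records$species)) {
    coh <- filter_samples(records[species == sp], species_label = sp)
    if (!any(coh$is_cns) || all(coh$is_cns))
      stop("species '", sp, "' lacks a CNS or non-CNS contrast group after filtering")
    tst <- wilcoxon_ranksum(coh$inex_ratio[coh$is_cns == TRUE],
                            coh$inex_ratio[coh$is_cns == FALSE], mode = mode)
    out[[sp]] <- data.table::data.table(
      species = sp, n_retained = nrow(coh),
      n_tissue_types = length(unique(coh$tissue_type)),
      p_value = tst$p_value, z_statistic = tst$z_statistic,
      effect_size_r = tst$effect_size_r)
  }
  data.table::rbindlist(out)
}
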