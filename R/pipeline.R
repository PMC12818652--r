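#' Pipeline configuration with the analysis defaults
#'
#' Defaults are the parameters of the published analysis: sample filters
#' TPM >= 1 and >= 3 junction-spanning reads; Wasserstein order p = 1;
#' complete-linkage clustering; exact Wilcoxon (auto fallback to the
#' tie-corrected normal approximation above N = 200); GSEA with minimum
#' set size 20, maximum 500, adjusted-p cutoff 0.01, seed 1111; motif
#' scanning with a 45-nt window, step 1 and minimum GU-run length 4.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tpm_min = 1, min_junction_reads = 3,
    count_mode = "unique_only",
    wasserstein_p = 1, linkage = "complete",
    bin_width = 0.1,
    wilcoxon_mode = "auto", exact_max_n = 200L,
    gsea_min_size = 20L, gsea_max_size = 500L,
    gsea_n_perm = 1000L, gsea_seed = 1111L, gsea_p_cutoff = 0.01,
    gsea_weight_p = 1, top_bottom_k = NULL,
    motif_window = 45L, motif_step = 1L, gu_min_len = 4L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Count junctions and build the filtered cohort
#'
#' Reads one `SJ.out.tab` per sample, classifies against the event, counts
#' inclusion/exclusion reads, joins sample metadata (tissue labels and
#' target-gene TPM), assigns the CNS flag from the tissue category, and
#' applies the sample filters. When `out_dir` is given, writes
#' `sample_counts.tsv`, `cohort.tsv` and `filter_report.tsv`.
#'
#' @param junction_files character vector of `SJ.out.tab` paths, named by
#'   sample id (unnamed: sample ids are the file base names minus
#'   `.SJ.out.tab`).
#' @param metadata a `data.frame` or TSV path with columns `sample_id`,
#'   `tissue_type`, `tissue_category`, `gene_tpm`.
#' @param event a [splice_site_spec()] (default [gnnk_event()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a list: `counts` (all samples), `cohort` (post-filter),
#'   `filter_report` (per-sample pass/fail with reasons).
#' @export
run_inex <- function(junction_files, metadata, event = gnnk_event(),
                     config = pipeline_config(), out_dir = NULL) {
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    metadata <- data.table::fread(metadata, sep = "\t", header = TRUE)
  }
  metadata <- data.table::as.data.table(metadata)
  need <- c("sample_id", "tissue_type", "tissue_category", "gene_tpm")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  ids <- names(junction_files)
  if (is.null(ids))
    ids <- sub("\\.SJ\\.out\\.tab$", "", basename(junction_files))
  counts <- data.table::rbindlist(lapply(seq_along(junction_files), function(i) {
    f <- junction_files[i]
    if (!file.exists(f)) stop("junction file not found: ", f)
    sj <- tryCatch(read_sj_tab(f),
                   error = function(e) stop("cannot parse ", f, ": ",
                                            conditionMessage(e)))
    count_sample_junctions(sj, event, count_mode = config$count_mode,
                           sample_id = ids[i])
  }))
  counts <- merge(counts, metadata, by = "sample_id", sort = TRUE)
  counts[, is_cns := assign_cns(tissue_category)]
  cohort <- filter_samples(counts, tpm_min = config$tpm_min,
                           min_junction_reads = config$min_junction_reads)
  report <- counts[, .(sample_id, tissue_type, gene_tpm,
                       total_reads = inclusion_reads + exclusion_reads)]
  report[, pass_tpm := gene_tpm >= config$tpm_min]
  report[, pass_reads := total_reads >= config$min_junction_reads]
  report[, retained := pass_tpm & pass_reads]
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    params <- config[c("tpm_min", "min_junction_reads", "count_mode")]
    write_tsv_prov(counts, file.path(out_dir, "sample_counts.tsv"), params)
    write_tsv_prov(cohort, file.path(out_dir, "cohort.tsv"), params)
    write_tsv_prov(report, file.path(out_dir, "filter_report.tsv"), params)
  }
  list(counts = counts, cohort = cohort, filter_report = report)
}

#' Compare tissue distributions of the in-ex ratio
#'
#' Pairwise W1 distance matrix between tissue types, complete-linkage
#' dendrogram, and the CNS vs non-CNS Wilcoxon rank-sum test with effect
#' size. When `out_dir` is given, writes `distance_matrix.tsv`,
#' `dendrogram.nwk` and `test_results.tsv`.
#'
#' @param cohort a filtered cohort table (from [run_inex()] or
#'   [filter_samples()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a list: `distance_matrix`, `hclust`, `newick`, `test`
#'   (a `data.table` row), `histograms` (per-tissue densities).
#' @export
run_compare <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  cohort <- data.table::as.data.table(cohort)
  if (length(unique(cohort$tissue_type)) < 2L)
    stop("need at least 2 tissue groups to compare")
  if (!any(cohort$is_cns) || all(cohort$is_cns))
    stop("missing contrast group: cohort needs both CNS and non-CNS samples")
  dm <- distance_matrix(cohort, p = config$wasserstein_p)
  hc <- complete_linkage_cluster(dm)
  nwk <- as_newick(hc)
  tst <- wilcoxon_ranksum(cohort$inex_ratio[cohort$is_cns == TRUE],
                          cohort$inex_ratio[cohort$is_cns == FALSE],
                          mode = config$wilcoxon_mode,
                          exact_max_n = config$exact_max_n)
  test_row <- data.table::data.table(
    group_a = "CNS", group_b = "non-CNS", n = tst$n_total,
    p_value = tst$p_value, z_statistic = tst$z_statistic,
    effect_size_r = tst$effect_size_r)
  hist <- tissue_distribution(cohort, bin_width = config$bin_width)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_distance_matrix(dm, file.path(out_dir, "distance_matrix.tsv"))
    writeLines(nwk, file.path(out_dir, "dendrogram.nwk"))
    write_test_results(test_row, file.path(out_dir, "test_results.tsv"))
    write_tsv_prov(hist, file.path(out_dir, "histograms.tsv"),
                   list(bin_width = config$bin_width))
  }
  list(distance_matrix = dm, hclust = hc, newick = nwk, test = test_row,
       histograms = hist)
}

#' Correlation-ranked gene-set enrichment over a cohort
#'
#' Ranks genes by Pearson correlation of expression with the in-ex ratio
#' across the cohort's samples, filters the gene-set collection to the
#' configured sizes, and runs pre-ranked GSEA. When `out_dir` is given,
#' writes `ranked_list.tsv` and `enrichment.tsv` (seed recorded in the
#' header).
#'
#' @param cohort a filtered cohort table.
#' @param expression sample x gene TPM matrix (rownames = sample ids).
#' @param gene_sets a named list of gene sets or a GMT file path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a list: `ranked` and `results`.
#' @export
run_gsea <- function(cohort, expression, gene_sets,
                     config = pipeline_config(), out_dir = NULL) {
  cohort <- data.table::as.data.table(cohort)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  inex <- stats::setNames(cohort$inex_ratio, cohort$sample_id)
  ranked <- correlate_genes(expression, inex)
  sets <- filter_gene_sets(gene_sets, ranked,
                           min_size = config$gsea_min_size,
                           max_size = config$gsea_max_size)
  if (!length(sets))
    stop("no gene set within size bounds [", config$gsea_min_size, ", ",
         config$gsea_max_size, "] after intersecting the ranked universe")
  results <- gsea_preranked(ranked, sets, weight_p = config$gsea_weight_p,
                            n_perm = config$gsea_n_perm,
                            seed = config$gsea_seed,
                            p_cutoff = config$gsea_p_cutoff,
                            top_bottom_k = config$top_bottom_k)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    params <- config[c("gsea_min_size", "gsea_max_size", "gsea_n_perm",
                       "gsea_seed", "gsea_p_cutoff")]
    write_ranked_list(ranked, file.path(out_dir, "ranked_list.tsv"))
    write_tsv_prov(results, file.path(out_dir, "enrichment.tsv"), params)
  }
  list(ranked = ranked, results = results)
}

#' Scan FASTA sequences for YCAY clusters and GU runs
#'
#' Runs the sliding-window YCAY scorer and GU-run detection on every
#' record of a FASTA file (or named character vector). Records shorter
#' than the window are skipped with a warning. When `out_dir` is given,
#' writes `ycay_track.tsv`, `ycay_track.bedGraph` and `gu_runs.bed`.
#'
#' @param fasta FASTA path or named character vector of sequences.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a list: `tracks` (one `data.table`, all records) and `gu_runs`.
#' @export
run_motifscan <- function(fasta, config = pipeline_config(),
                          out_dir = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ds <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ds), names(ds))
  } else {
    seqs <- fasta
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  tracks <- list(); runs <- list()
  for (id in names(seqs)) {
    if (nchar(seqs[[id]]) < config$motif_window) {
      warning("record '", id, "' shorter than the ", config$motif_window,
              "-nt window; skipped")
      next
    }
    tracks[[id]] <- scan_sequence(seqs[[id]], window = config$motif_window,
                                  step = config$motif_step,
                                  sequence_id = id)
    runs[[id]] <- find_gu_runs(seqs[[id]], min_len = config$gu_min_len,
                               sequence_id = id)
  }
  if (!length(tracks)) stop("no record long enough to scan")
  tracks <- data.table::rbindlist(tracks)
  runs <- data.table::rbindlist(runs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    params <- config[c("motif_window", "motif_step", "gu_min_len")]
    write_track_tsv(tracks, file.path(out_dir, "ycay_track.tsv"))
    write_track_bedgraph(tracks, file.path(out_dir, "ycay_track.bedGraph"))
    write_gu_bed(runs, file.path(out_dir, "gu_runs.bed"))
  }
  list(tracks = tracks, gu_runs = runs)
}
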