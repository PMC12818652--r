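#' Default simulated tissue panel
#'
#' Two CNS tissues with inclusion probability 0.7 and two non-CNS tissues
#' with 0.2, 25 samples each (50 per class): the CNS-shifted inclusion
#' structure the analysis is designed to detect.
#'
#' @return a `data.frame` with `name`, `n_samples`, `inclusion_prob`,
#'   `is_cns`.
#' @export
default_tissues <- function() {
  data.frame(
    name = c("forebrain", "hindbrain", "liver", "heart"),
    n_samples = c(25L, 25L, 25L, 25L),
    inclusion_prob = c(0.7, 0.7, 0.2, 0.2),
    is_cns = c(TRUE, TRUE, FALSE, FALSE))
}

#' Default simulated gene panel
#'
#' 20 genes rising with the in-ex ratio (the "CNS-like" panel), 20 falling,
#' and 20 unrelated, each following
#' `TPM = baseline + slope * inex + N(0, noise_sd)`.
#'
#' @param n_pos,n_neg,n_null panel sizes per class.
#' @param baseline,slope,noise_sd linear-model parameters (TPM units).
#' @return a `data.frame` with `gene_id`, `baseline`, `slope`, `noise_sd`.
#' @export
default_gene_panel <- function(n_pos = 20L, n_neg = 20L, n_null = 20L,
                               baseline = 50, slope = 30, noise_sd = 10) {
  data.frame(
    gene_id = c(sprintf("POSG%02d", seq_len(n_pos)),
                sprintf("NEGG%02d", seq_len(n_neg)),
                sprintf("NULG%02d", seq_len(n_null))),
    baseline = baseline,
    slope = c(rep(slope, n_pos), rep(-slope, n_neg), rep(0, n_null)),
    noise_sd = noise_sd)
}

#' Default sequence plan for motif fixtures
#'
#' One 420-nt sequence with planted YCAY clusters of known pattern score
#' (8, 4, 2) and one GU run of 6 nt, spaced so that no 45-nt window spans
#' two planted elements; the background is free of YCAY motifs and GU runs.
#'
#' @return a `data.frame` with `sequence_id`, `element`, `start`, `param`.
#' @export
default_motif_plan <- function() {
  data.frame(
    sequence_id = "KITsyn_flank",
    element = c("triple_tight", "triple_mixed", "triple_tight_far", "gu_run"),
    start = c(60L, 140L, 220L, 320L),
    param = c(NA_integer_, NA_integer_, NA_integer_, 6L))
}

#' Simulation configuration
#'
#' All randomness in [simulate_cohort()], [simulate_expression()] and
#' [simulate_sequences()] flows from `seed`. Junction depth per sample is
#' negative binomial (`depth_mean`, `depth_dispersion`), emulating uneven
#' RNA-seq coverage (Poisson is the dispersion to infinity limit);
#' inclusion reads are binomial with the tissue's inclusion probability;
#' target-gene TPM is gamma with mean `tpm_mean` and sd `tpm_sd`.
#'
#' @param seed integer master seed.
#' @param tissues tissue panel ([default_tissues()] layout).
#' @param depth_mean expected junction-spanning reads per sample.
#' @param depth_dispersion negative-binomial size parameter.
#' @param tpm_mean,tpm_sd target-gene TPM distribution (TPM units).
#' @param gene_panel gene panel ([default_gene_panel()] layout).
#' @param motif_plan sequence plan ([default_motif_plan()] layout).
#' @param seq_len length of each simulated sequence (nt).
#' @param n_decoy decoy junction rows per SJ file exercising the `OTHER`
#'   classification path (acceptor mismatch, foreign chromosome).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, tissues = default_tissues(),
                       depth_mean = 100, depth_dispersion = 10,
                       tpm_mean = 30, tpm_sd = 15,
                       gene_panel = default_gene_panel(),
                       motif_plan = default_motif_plan(),
                       seq_len = 420L, n_decoy = 2L) {
  tissues <- as.data.frame(tissues)
  stopifnot(all(c("name", "n_samples", "inclusion_prob", "is_cns") %in%
                  names(tissues)),
            all(tissues$n_samples >= 1L), depth_mean > 0,
            depth_dispersion > 0, tpm_mean > 0, tpm_sd > 0)
  if (any(tissues$inclusion_prob < 0 | tissues$inclusion_prob > 1))
    stop("inclusion probabilities must lie in [0, 1]")
  if (!n_decoy %in% 0:2) stop("n_decoy must be 0, 1 or 2")
  structure(list(seed = as.integer(seed), tissues = tissues,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 tpm_mean = tpm_mean, tpm_sd = tpm_sd,
                 gene_panel = as.data.frame(gene_panel),
                 motif_plan = as.data.frame(motif_plan),
                 seq_len = as.integer(seq_len),
                 n_decoy = as.integer(n_decoy)),
            class = "sim_config")
}

#' Simulate a cohort of samples with junction evidence
#'
#' Per sample: total junction reads `n_i ~ NegBin(depth_mean,
#' depth_dispersion)`, inclusion reads `~ Binomial(n_i, p_t)` with the
#' tissue's inclusion probability, exclusion the remainder, target-gene
#' TPM from the configured gamma. When `dir` is given, one STAR-dialect
#' `SJ.out.tab` file per sample is written containing the two event rows
#' (SDS1-SAS, SDS2-SAS of [gnnk_event()]) plus decoy junctions, together
#' with `metadata.tsv` and `manifest.tsv`. Identical seeds yield
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @return a `data.table` of sample records (`sample_id`, `tissue_type`,
#'   `tissue_category`, `is_cns`, `inclusion_reads`, `exclusion_reads`,
#'   `inex_ratio`, `gene_tpm`); attribute `sj_files` when files were
#'   written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  event <- gnnk_event()
  records <- with_local_seed(config$seed, {
    out <- list()
    for (t in seq_len(nrow(config$tissues))) {
      ti <- config$tissues[t, ]
      for (s in seq_len(ti$n_samples)) {
        n_i <- rnbinom(1L, size = config$depth_dispersion,
                       mu = config$depth_mean)
        inc <- rbinom(1L, n_i, ti$inclusion_prob)
        shape <- (config$tpm_mean / config$tpm_sd)^2
        rate <- config$tpm_mean / config$tpm_sd^2
        tpm <- rgamma(1L, shape = shape, rate = rate)
        decoy <- stats::rpois(config$n_decoy, lambda = 5) + 1L
        out[[length(out) + 1L]] <- list(
          sample_id = sprintf("%s_%02d", ti$name, s),
          tissue_type = ti$name, tissue_category = ti$name,
          is_cns = ti$is_cns,
          inclusion_reads = as.integer(inc),
          exclusion_reads = as.integer(n_i - inc),
          gene_tpm = tpm, decoy = list(decoy))
      }
    }
    data.table::rbindlist(out)
  })
  records[, inex_ratio := compute_inex_ratio(inclusion_reads,
                                             exclusion_reads)]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(nrow(records))
    for (i in seq_len(nrow(records))) {
      decoy <- records$decoy[[i]]
      sj <- data.table::data.table(
        chrom = c(event$chrom, event$chrom, event$chrom, "chr_decoy"),
        intron_start = c(event$sds2, event$sds1, event$sds2, 500L),
        intron_end = c(event$sas, event$sas, event$sas - 100L, 800L),
        strand_code = c(1L, 1L, 1L, 2L),
        motif = 1L, annotated = 1L,
        unique_reads = c(records$inclusion_reads[i],
                         records$exclusion_reads[i],
                         decoy[1], decoy[min(2L, length(decoy))]),
        multimap_reads = 0L, max_overhang = 30L)
      sj <- sj[seq_len(2L + config$n_decoy)]
      files[i] <- file.path(dir, paste0(records$sample_id[i], ".SJ.out.tab"))
      data.table::fwrite(sj, files[i], sep = "\t", col.names = FALSE)
    }
    meta <- records[, .(sample_id, tissue_type, tissue_category, gene_tpm)]
    data.table::fwrite(meta, file.path(dir, "metadata.tsv"), sep = "\t")
    manifest <- data.table::data.table(sample_id = records$sample_id,
                                       sj_file = basename(files))
    data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
    data.table::setattr(records, "sj_files",
                        stats::setNames(files, records$sample_id))
  }
  records[, decoy := NULL]
  records[]
}

#' Simulate a sample x gene expression matrix
#'
#' Each panel gene follows `TPM = baseline + slope * inex + N(0,
#' noise_sd)` in the cohort's realised in-ex ratios. Samples with an
#' undefined ratio (zero depth) contribute at `inex = 0`. Negative draws
#' are clipped at 0 (count reported via `options(inexr.verbose = TRUE)`)
#' unless `clip_negative = FALSE`.
#'
#' @param config a [sim_config()].
#' @param cohort records from [simulate_cohort()].
#' @param clip_negative clip negative TPM draws at zero (default TRUE).
#' @return numeric matrix, samples in rows (rownames = sample ids), genes
#'   in columns.
#' @export
simulate_expression <- function(config, cohort, clip_negative = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- data.table::as.data.table(cohort)
  inex <- cohort$inex_ratio
  n_undef <- sum(!is.finite(inex))
  if (n_undef) verbose_msg(n_undef, " sample(s) with undefined ratio set to inex = 0")
  inex[!is.finite(inex)] <- 0
  panel <- config$gene_panel
  M <- with_local_seed(config$seed + 1L, {
    vapply(seq_len(nrow(panel)), function(g) {
      panel$baseline[g] + panel$slope[g] * inex +
        rnorm(length(inex), 0, panel$noise_sd[g])
    }, numeric(length(inex)))
  })
  if (clip_negative) {
    nneg <- sum(M < 0)
    if (nneg) verbose_msg(nneg, " negative TPM draw(s) clipped at 0")
    M[M < 0] <- 0
  }
  dimnames(M) <- list(cohort$sample_id, panel$gene_id)
  M
}

#' Gene set of the positive-slope panel genes
#'
#' The simulated analogue of a CNS-associated gene set: the panel genes
#' whose expression rises with the in-ex ratio.
#'
#' @param config a [sim_config()].
#' @return a named list with one element `CNS_like` (gene ids).
#' @export
cns_like_set <- function(config) {
  list(CNS_like = config$gene_panel$gene_id[config$gene_panel$slope > 0])
}

# Planted-element building blocks (DNA alphabet; background AAGC repeats
# contain no YCAY and no GU run of length >= 2).
motif_element_seq <- function(element, param = NA_integer_) {
  switch(element,
    triple_tight     = "TCATAATCATAATCAT",          # gaps (2, 2) -> 8
    triple_mixed     = "TCATAAATCATAATCAT",         # gaps (3, 2) -> 4
    triple_tight_far = "TCATAATCATAAAAAAATCAT",     # gaps (2, 7) -> 2
    triple_mid_far   = "TCATAAATCATAAAAAAATCAT",    # gaps (3, 7) -> 1
    pair_far         = "TCATAAAAAAATCAT",           # gap 7       -> 0
    gu_run = {
      if (is.na(param) || param < 4L) stop("gu_run needs param >= 4")
      # single-A guards keep the run maximal against any background base
      paste0("A", substr(strrep("GT", param), 1L, param), "A")
    },
    stop("unknown planted element: ", element))
}

motif_element_raw <- function(element) {
  c(triple_tight = 8L, triple_mixed = 4L, triple_tight_far = 2L,
    triple_mid_far = 1L, pair_far = 0L, gu_run = NA_integer_)[[element]]
}

#' Simulate sequences with planted YCAY clusters and GU runs
#'
#' Builds each planned sequence on a YCAY-free, GU-run-free background
#' (`AAGC` repeats), overwrites the planted elements at their positions,
#' and verifies the result: planted elements must not overlap, the
#' greedy motif scan of the full sequence must find exactly the planted
#' motifs, and GU-run detection must find exactly the planted runs. A
#' truth table records each element's expected raw window score under the
#' scoring rules.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; writes `sequences.fa` (DNA,
#'   via Biostrings) and `motif_truth.tsv`.
#' @return a list: `sequences` (named character) and `truth`
#'   (`data.table`: `sequence_id`, `element`, `start`, `length`,
#'   `expected_raw`).
#' @export
simulate_sequences <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  plan <- data.table::as.data.table(config$motif_plan)
  seqs <- list(); truth <- list()
  for (sid in unique(plan$sequence_id)) {
    p <- plan[sequence_id == sid]
    bg <- substr(strrep("AAGC", ceiling(config$seq_len / 4)), 1L,
                 config$seq_len)
    chars <- strsplit(bg, "", fixed = TRUE)[[1]]
    expected_starts <- integer(0)
    iv <- matrix(numeric(0), ncol = 2)
    for (e in seq_len(nrow(p))) {
      el <- motif_element_seq(p$element[e], p$param[e])
      st <- p$start[e]                               # 0-based
      en <- st + nchar(el)
      if (en > config$seq_len)
        stop("planted element exceeds sequence length")
      if (nrow(iv) && any(pmax(iv[, 1], st) < pmin(iv[, 2], en)))
        stop("planted elements overlap")
      iv <- rbind(iv, c(st, en))
      chars[(st + 1L):en] <- strsplit(el, "", fixed = TRUE)[[1]]
      if (p$element[e] != "gu_run") {
        expected_starts <- c(expected_starts, st + find_ycay_sites(el))
        truth[[length(truth) + 1L]] <- data.table::data.table(
          sequence_id = sid, element = p$element[e], start = st,
          length = nchar(el), expected_raw = motif_element_raw(p$element[e]))
      } else {
        # the recorded interval is the run itself, inside the A guards
        truth[[length(truth) + 1L]] <- data.table::data.table(
          sequence_id = sid, element = "gu_run", start = st + 1L,
          length = as.integer(p$param[e]),
          expected_raw = NA_integer_)
      }
    }
    s <- paste(chars, collapse = "")
    found <- find_ycay_sites(s)
    if (!identical(sort(as.integer(found)), sort(as.integer(expected_starts))))
      stop("background/planting interaction produced stray YCAY motifs")
    runs <- find_gu_runs(s)
    planted_gu <- p[element == "gu_run"]
    if (nrow(runs) != nrow(planted_gu) ||
        (nrow(runs) && (!identical(sort(runs$start),
                                   sort(as.integer(planted_gu$start) + 1L)) ||
                        !identical(sort(runs$length),
                                   sort(as.integer(planted_gu$param))))))
      stop("background/planting interaction produced stray GU runs")
    seqs[[sid]] <- s
  }
  truth <- data.table::rbindlist(truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ds <- Biostrings::DNAStringSet(unlist(seqs))
    Biostrings::writeXStringSet(ds, file.path(dir, "sequences.fa"))
    data.table::fwrite(truth, file.path(dir, "motif_truth.tsv"), sep = "\t")
  }
  list(sequences = unlist(seqs), truth = truth)
}
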