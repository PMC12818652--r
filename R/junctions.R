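#' Define an alternative 5' splice-donor event
#'
#' An event consists of two alternative donor sites (SDS1 upstream, SDS2
#' downstream on the transcribed strand) feeding one shared acceptor (SAS).
#' Coordinates follow the STAR `SJ.out.tab` convention: 1-based, with a
#' donor-site coordinate giving the first intronic base of the intron that
#' starts there and the acceptor coordinate giving the last intronic base.
#' Use of the upstream donor (the longer intron) excludes the inter-donor
#' segment from the mature mRNA; use of the downstream donor includes it.
#'
#' @param chrom sequence (chromosome) name.
#' @param strand `"+"` or `"-"`, the transcribed strand of the host gene.
#' @param sds1 first intronic base when the upstream (exclusion) donor is
#'   used.
#' @param sds2 first intronic base when the downstream (inclusion) donor is
#'   used. On the `-` strand "downstream" means a smaller genomic coordinate.
#' @param sas last intronic base at the shared acceptor.
#' @param gene_id identifier of the host gene.
#' @return an object of class `splice_site_spec`.
#' @examples
#' splice_site_spec("chr4", "+", sds1 = 100, sds2 = 112, sas = 500, gene_id = "KIT")
#' @export
splice_site_spec <- function(chrom, strand, sds1, sds2, sas, gene_id = NA_character_) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.numeric(sds1), is.numeric(sds2), is.numeric(sas),
            length(chrom) == 1L, sds1 != sds2)
  if (strand == "+") {
    if (!(sds1 < sds2 && sds2 < sas))
      stop("on '+' strand the event must satisfy sds1 < sds2 < sas")
  } else {
    if (!(sds1 > sds2 && sds2 > sas))
      stop("on '-' strand the event must satisfy sds1 > sds2 > sas (genomic coordinates)")
  }
  structure(list(chrom = as.character(chrom), strand = strand,
                 sds1 = as.integer(sds1), sds2 = as.integer(sds2),
                 sas = as.integer(sas), gene_id = as.character(gene_id)),
            class = "splice_site_spec")
}

#' @export
print.splice_site_spec <- function(x, ...) {
  cat(sprintf("<splice_site_spec> %s (%s%s)  SDS1=%d  SDS2=%d  SAS=%d  offset=%d nt\n",
              x$gene_id, x$chrom, x$strand, x$sds1, x$sds2, x$sas,
              donor_offset(x)))
  invisible(x)
}

#' Offset between the two alternative donor sites
#'
#' @param event a [splice_site_spec()].
#' @return absolute distance in nucleotides between SDS1 and SDS2.
#' @export
donor_offset <- function(event) abs(event$sds2 - event$sds1)

#' Packaged synthetic KIT-like GN[N/S]K event
#'
#' A synthetic stand-in event with the geometry of the KIT GN[N/S]K
#' alternative 5' donor pair: two GT donors 12 nt apart (4 codons) feeding
#' one shared acceptor. Coordinates refer to the synthetic locus emitted by
#' [simulate_cohort()] and [simulate_sequences()], not to any reference
#' genome; supply real coordinates via [splice_site_spec()] when analysing
#' aligned data.
#'
#' @return a [splice_site_spec()].
#' @export
gnnk_event <- function() {
  splice_site_spec(chrom = "KITsyn", strand = "+",
                   sds1 = 1201L, sds2 = 1213L, sas = 1800L,
                   gene_id = "KIT")
}

#' Read a STAR SJ.out.tab splice-junction table
#'
#' Nine tab-separated columns with STAR semantics: chrom, 1-based first and
#' last intronic base, strand code (0 undefined, 1 `+`, 2 `-`), intron motif
#' code, annotation flag, uniquely-mapping read count, multi-mapping read
#' count, maximum spliced-alignment overhang.
#'
#' @param path file path.
#' @return a `data.table` with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`"+"`, `"-"` or `"*"`), `motif`, `annotated`, `unique_reads`,
#'   `multimap_reads`, `max_overhang`.
#' @export
read_sj_tab <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "intron_start", "intron_end", "strand_code",
                  "motif", "annotated", "unique_reads", "multimap_reads",
                  "max_overhang"))
  if (ncol(dt) != 9L)
    stop("not an SJ.out.tab file (expected 9 columns): ", path)
  dt[, strand := c("*", "+", "-")[strand_code + 1L]]
  dt[, strand_code := NULL]
  data.table::setcolorder(dt, c("chrom", "intron_start", "intron_end",
                                "strand", "motif", "annotated",
                                "unique_reads", "multimap_reads",
                                "max_overhang"))
  dt[]
}

#' Read a BED-like junction table
#'
#' Generic six-column BED (chrom, start, end, name, score, strand) where
#' each record is an intron in 0-based half-open coordinates and `score`
#' carries the supporting read count. Converted internally to the 1-based
#' inclusive convention; the read count is taken as uniquely mapping.
#'
#' @param path file path.
#' @return a `data.table` in the same layout as [read_sj_tab()].
#' @export
read_junction_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("junction BED needs at least 6 columns: ", path)
  data.table::setnames(dt, 1:6,
    c("chrom", "start0", "end0", "name", "score", "strand"))
  conv <- from_bed0(dt$start0, dt$end0)
  data.table::data.table(
    chrom = dt$chrom,
    intron_start = as.integer(conv$start), intron_end = as.integer(conv$end),
    strand = ifelse(dt$strand %in% c("+", "-"), dt$strand, "*"),
    motif = NA_integer_, annotated = NA_integer_,
    unique_reads = as.integer(dt$score), multimap_reads = 0L,
    max_overhang = NA_integer_)
}

#' Classify junction records against an alternative-donor event
#'
#' On the `+` strand the donor-side intron boundary is `intron_start` and
#' the acceptor-side boundary is `intron_end`; on the `-` strand these roles
#' swap. A record is `INCLUSION` when its donor boundary equals SDS2 and its
#' acceptor boundary equals SAS, `EXCLUSION` for SDS1/SAS, and `OTHER`
#' otherwise (including chromosome mismatches). Records with undefined
#' strand are classified by coordinates alone, which the event's own strand
#' already fixes.
#'
#' @param junctions a junction `data.table` as returned by [read_sj_tab()],
#'   or anything coercible with the columns `chrom`, `intron_start`,
#'   `intron_end`.
#' @param event a [splice_site_spec()].
#' @return a character vector (one label per record) in
#'   `{"INCLUSION","EXCLUSION","OTHER"}`.
#' @export
classify_junction <- function(junctions, event) {
  stopifnot(inherits(event, "splice_site_spec"))
  junctions <- data.table::as.data.table(junctions)
  if (event$strand == "+") {
    donor <- junctions$intron_start; acceptor <- junctions$intron_end
  } else {
    donor <- junctions$intron_end; acceptor <- junctions$intron_start
  }
  same_chrom <- junctions$chrom == event$chrom
  lab <- rep("OTHER", nrow(junctions))
  lab[same_chrom & donor == event$sds2 & acceptor == event$sas] <- "INCLUSION"
  lab[same_chrom & donor == event$sds1 & acceptor == event$sas] <- "EXCLUSION"
  lab
}

#' Count inclusion/exclusion junction reads for one sample
#'
#' Sums the selected read-count field over all records classified
#' `INCLUSION` ([SDS2&SAS]) and `EXCLUSION` ([SDS1&SAS]); multiple records
#' matching the same junction are summed. Malformed records
#' (`intron_start > intron_end`) are rejected with a warning.
#'
#' @param junctions one sample's junction table ([read_sj_tab()] layout).
#' @param event a [splice_site_spec()].
#' @param count_mode `"unique_only"` (STAR column 7, the default) or
#'   `"unique_plus_multi"`.
#' @param sample_id identifier recorded in the result.
#' @return a one-row `data.table` with `sample_id`, `inclusion_reads`,
#'   `exclusion_reads`, `inex_ratio` (`NA` when both counts are zero).
#' @export
count_sample_junctions <- function(junctions, event,
                                   count_mode = c("unique_only",
                                                  "unique_plus_multi"),
                                   sample_id = NA_character_) {
  count_mode <- match.arg(count_mode)
  junctions <- data.table::as.data.table(junctions)
  if (nrow(junctions)) {
    bad <- junctions$intron_start > junctions$intron_end
    if (any(bad)) {
      warning(sum(bad), " junction record(s) with intron_start > intron_end rejected")
      junctions <- junctions[!bad]
    }
  }
  if (!nrow(junctions)) {
    inc <- exc <- 0L
  } else {
    reads <- junctions$unique_reads
    if (count_mode == "unique_plus_multi") reads <- reads + junctions$multimap_reads
    lab <- classify_junction(junctions, event)
    inc <- sum(reads[lab == "INCLUSION"])
    exc <- sum(reads[lab == "EXCLUSION"])
  }
  data.table::data.table(sample_id = sample_id,
                         inclusion_reads = as.integer(inc),
                         exclusion_reads = as.integer(exc),
                         inex_ratio = compute_inex_ratio(inc, exc))
}

#' Compute the in-ex ratio
#'
#' `(inclusion - exclusion) / (inclusion + exclusion)`, the signed balance
#' of downstream-donor (inclusion, [SDS2&SAS]) over upstream-donor
#' (exclusion, [SDS1&SAS]) junction reads. Equals +1 when every read
#' supports inclusion (all GN[N/S]K+), -1 when every read supports
#' exclusion, and is undefined (`NA`) when both counts are zero.
#'
#' @param inclusion_reads,exclusion_reads non-negative read counts
#'   (vectorised).
#' @return numeric in `[-1, 1]`, `NA` where both counts are zero.
#' @examples
#' compute_inex_ratio(10, 0)  # +1
#' compute_inex_ratio(3, 1)   # 0.5
#' @export
compute_inex_ratio <- function(inclusion_reads, exclusion_reads) {
  if (any(inclusion_reads < 0, na.rm = TRUE) ||
      any(exclusion_reads < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  tot <- inclusion_reads + exclusion_reads
  ifelse(tot > 0, (inclusion_reads - exclusion_reads) / tot, NA_real_)
}

#' Write / read per-sample junction count tables
#'
#' TSV with columns `sample_id`, `inclusion_reads`, `exclusion_reads`,
#' `inex_ratio`. On reading, the ratio is recomputed from the integer
#' counts, so round-tripping reproduces ratios bit-for-bit regardless of
#' the decimal rendering in the file.
#'
#' @param counts a `data.table` of per-sample counts.
#' @param path file path.
#' @return `write_sample_counts()` the path, invisibly;
#'   `read_sample_counts()` a `data.table`.
#' @export
write_sample_counts <- function(counts, path) {
  cols <- c("sample_id", "inclusion_reads", "exclusion_reads", "inex_ratio")
  write_tsv_prov(data.table::as.data.table(counts)[, cols, with = FALSE], path)
}

#' @rdname write_sample_counts
#' @export
read_sample_counts <- function(path) {
  dt <- read_tsv_prov(path)
  need <- c("sample_id", "inclusion_reads", "exclusion_reads")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dt[, inex_ratio := compute_inex_ratio(inclusion_reads, exclusion_reads)]
  dt[]
}
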