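event_plus <- splice_site_spec("chrT", "+", sds1 = 100, sds2 = 112,
                               sas = 500, gene_id = "KIT")

make_junction <- function(start, end, chrom = "chrT", strand = "+",
                          unique = 5L, multi = 0L) {
  data.frame(chrom = chrom, intron_start = start, intron_end = end,
             strand = strand, unique_reads = unique, multimap_reads = multi)
}

test_that("junction classification distinguishes inclusion, exclusion, other", {
  expect_equal(classify_junction(make_junction(112, 500), event_plus),
               "INCLUSION")
  expect_equal(classify_junction(make_junction(100, 500), event_plus),
               "EXCLUSION")
  expect_equal(classify_junction(make_junction(100, 450), event_plus),
               "OTHER")                               # acceptor mismatch
  expect_equal(classify_junction(make_junction(112, 500, chrom = "chrX"),
                                 event_plus), "OTHER") # chromosome mismatch
  # undefined strand records classify by coordinates alone
  expect_equal(classify_junction(make_junction(112, 500, strand = "*"),
                                 event_plus), "INCLUSION")
})

test_that("minus-strand events swap donor and acceptor intron boundaries", {
  ev <- splice_site_spec("chrT", "-", sds1 = 900, sds2 = 888, sas = 300)
  expect_equal(classify_junction(make_junction(300, 888), ev), "INCLUSION")
  expect_equal(classify_junction(make_junction(300, 900), ev), "EXCLUSION")
  expect_equal(classify_junction(make_junction(310, 900), ev), "OTHER")
})

test_that("classification partitions any evidence set into exactly one label", {
  set.seed(11)
  j <- data.frame(chrom = sample(c("chrT", "chrX"), 50, TRUE),
                  intron_start = sample(c(100L, 112L, 90L), 50, TRUE),
                  intron_end = sample(c(500L, 450L), 50, TRUE),
                  strand = "+", unique_reads = 1L, multimap_reads = 0L)
  lab <- classify_junction(j, event_plus)
  expect_length(lab, 50)
  expect_true(all(lab %in% c("INCLUSION", "EXCLUSION", "OTHER")))
})

test_that("event geometry is validated and the packaged event has a 12-nt donor offset", {
  expect_error(splice_site_spec("c", "+", sds1 = 112, sds2 = 100, sas = 500),
               "sds1 < sds2")
  ev <- gnnk_event()
  expect_s3_class(ev, "splice_site_spec")
  expect_identical(donor_offset(ev), 12L)
})

test_that("per-sample counting sums matching records and handles empty input", {
  j <- rbind(make_junction(112, 500, unique = 4L),
             make_junction(112, 500, unique = 2L),
             make_junction(100, 500, unique = 3L),
             make_junction(100, 450, unique = 9L))
  cnt <- count_sample_junctions(j, event_plus, sample_id = "s1")
  expect_identical(cnt$inclusion_reads, 6L)   # additivity over duplicates
  expect_identical(cnt$exclusion_reads, 3L)
  expect_equal(cnt$inex_ratio, (6 - 3) / (6 + 3))

  only_other <- make_junction(90, 450)
  cnt0 <- count_sample_junctions(only_other, event_plus)
  expect_identical(c(cnt0$inclusion_reads, cnt0$exclusion_reads), c(0L, 0L))
  expect_true(is.na(cnt0$inex_ratio))

  empty <- count_sample_junctions(make_junction(1, 2)[0, ], event_plus)
  expect_identical(c(empty$inclusion_reads, empty$exclusion_reads), c(0L, 0L))
})

test_that("multimapping reads contribute only in unique_plus_multi mode", {
  j <- make_junction(112, 500, unique = 4L, multi = 6L)
  expect_identical(count_sample_junctions(j, event_plus)$inclusion_reads, 4L)
  expect_identical(
    count_sample_junctions(j, event_plus,
                           count_mode = "unique_plus_multi")$inclusion_reads,
    10L)
})

test_that("malformed junction records are rejected with a warning", {
  j <- rbind(make_junction(112, 500), make_junction(600, 500))
  expect_warning(cnt <- count_sample_junctions(j, event_plus),
                 "rejected")
  expect_identical(cnt$inclusion_reads, 5L)
})

test_that("in-ex ratio matches its definition, endpoints and edge cases", {
  expect_identical(compute_inex_ratio(10, 0), 1)
  expect_identical(compute_inex_ratio(0, 5), -1)
  expect_equal(compute_inex_ratio(3, 1), 0.5)
  expect_equal(compute_inex_ratio(2, 2), 0)
  expect_true(is.na(compute_inex_ratio(0, 0)))   # undefined, never 0
  expect_error(compute_inex_ratio(-1, 2), "non-negative")
})

test_that("in-ex ratio is antisymmetric, scale-invariant and bounded", {
  set.seed(21)
  for (rep in 1:50) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    if (a + b == 0) b <- 1
    r <- compute_inex_ratio(a, b)
    expect_equal(r, -compute_inex_ratio(b, a))
    expect_true(r >= -1 && r <= 1)
    k <- sample(2:9, 1)
    expect_equal(compute_inex_ratio(k * a, k * b), r)
  }
})

test_that("SJ.out.tab reading maps STAR strand codes and columns", {
  f <- tempfile(fileext = ".SJ.out.tab")
  writeLines(c("chrT\t112\t500\t1\t1\t1\t7\t2\t30",
               "chrT\t100\t500\t2\t1\t1\t3\t0\t25",
               "chrX\t10\t20\t0\t0\t0\t1\t0\t10"), f)
  sj <- read_sj_tab(f)
  expect_identical(sj$strand, c("+", "-", "*"))
  expect_identical(sj$unique_reads, c(7L, 3L, 1L))
  expect_identical(sj$intron_start, c(112L, 100L, 10L))
})

test_that("BED-like junction tables convert to 1-based inclusive introns", {
  f <- tempfile(fileext = ".bed")
  writeLines("chrT\t111\t500\tjx1\t7\t+", f)
  dt <- read_junction_bed(f)
  expect_identical(dt$intron_start, 112L)
  expect_identical(dt$intron_end, 500L)
  expect_identical(dt$unique_reads, 7L)
  expect_equal(classify_junction(dt, event_plus), "INCLUSION")
})

test_that("count tables round-trip through TSV with bit-identical ratios", {
  counts <- data.table::data.table(
    sample_id = sprintf("s%d", 1:5),
    inclusion_reads = c(7L, 1L, 0L, 13L, 2L),
    exclusion_reads = c(3L, 2L, 9L, 0L, 2L))
  counts[, inex_ratio := compute_inex_ratio(inclusion_reads,
                                            exclusion_reads)]
  f <- tempfile(fileext = ".tsv")
  write_sample_counts(counts, f)
  back <- read_sample_counts(f)
  expect_identical(back$inex_ratio, counts$inex_ratio)
  expect_identical(back$inclusion_reads, counts$inclusion_reads)
})
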