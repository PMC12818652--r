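test_that("simulation is fully reproducible from the seed, including files", {
  cfg <- sim_config(seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate inclusion probabilities give endpoint ratios", {
  tis <- data.frame(name = "brain", n_samples = 30L, inclusion_prob = 1,
                    is_cns = TRUE)
  coh <- simulate_cohort(sim_config(seed = 3, tissues = tis))
  expect_true(all(coh$inex_ratio[is.finite(coh$inex_ratio)] == 1))
  tis$inclusion_prob <- 0
  coh0 <- simulate_cohort(sim_config(seed = 3, tissues = tis))
  expect_true(all(coh0$inex_ratio[is.finite(coh0$inex_ratio)] == -1))
})

test_that("balanced inclusion at depth 1000 centres the cohort ratio", {
  tis <- data.frame(name = "t", n_samples = 200L, inclusion_prob = 0.5,
                    is_cns = FALSE)
  coh <- simulate_cohort(sim_config(seed = 11, tissues = tis,
                                    depth_mean = 1000))
  expect_lt(abs(mean(coh$inex_ratio, na.rm = TRUE)), 0.05)
})

test_that("mean ratio approaches 2p - 1 as depth grows", {
  tis <- data.frame(name = c("cns", "per"), n_samples = c(25L, 25L),
                    inclusion_prob = c(0.7, 0.2), is_cns = c(TRUE, FALSE))
  coh <- simulate_cohort(sim_config(seed = 13, tissues = tis,
                                    depth_mean = 1e4,
                                    depth_dispersion = 50))
  m <- tapply(coh$inex_ratio, coh$tissue_type, mean, na.rm = TRUE)
  expect_equal(unname(m["cns"]), 2 * 0.7 - 1, tolerance = 0.01)
  expect_equal(unname(m["per"]), 2 * 0.2 - 1, tolerance = 0.01)
})

test_that("invalid configurations are rejected", {
  tis <- default_tissues()
  tis$inclusion_prob[1] <- 1.4
  expect_error(sim_config(tissues = tis), "\\[0, 1\\]")
  expect_error(sim_config(n_decoy = 5), "n_decoy")
})

test_that("SJ files reproduce the cohort counts through the junction reader", {
  dir <- tempfile()
  cfg <- sim_config(seed = 17)
  coh <- simulate_cohort(cfg, dir = dir)
  files <- attr(coh, "sj_files")
  ev <- gnnk_event()
  for (i in sample(nrow(coh), 5)) {
    sj <- read_sj_tab(files[[coh$sample_id[i]]])
    expect_identical(nrow(sj), 4L)   # 2 event rows + 2 decoys
    lab <- classify_junction(sj, ev)
    expect_identical(sum(lab == "OTHER"), 2L)
    cnt <- count_sample_junctions(sj, ev, sample_id = coh$sample_id[i])
    expect_identical(cnt$inclusion_reads, coh$inclusion_reads[i])
    expect_identical(cnt$exclusion_reads, coh$exclusion_reads[i])
    expect_identical(cnt$inex_ratio, coh$inex_ratio[i])
  }
})

test_that("tissue inclusion probabilities are recovered within 3 binomial SEs", {
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed)
    coh <- simulate_cohort(cfg)
    for (t in seq_len(nrow(cfg$tissues))) {
      ti <- cfg$tissues[t, ]
      sub <- coh[coh$tissue_type == ti$name, ]
      n_tot <- sum(sub$inclusion_reads + sub$exclusion_reads)
      p_hat <- sum(sub$inclusion_reads) / n_tot
      se <- sqrt(ti$inclusion_prob * (1 - ti$inclusion_prob) / n_tot)
      total <- total + 1L
      if (abs(p_hat - ti$inclusion_prob) <= 3 * se) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("expression follows the configured linear model in the ratio", {
  panel <- data.frame(gene_id = c("up", "dn", "nil"),
                      baseline = 50, slope = c(20, -20, 0),
                      noise_sd = 0)
  cfg <- sim_config(seed = 19, gene_panel = panel)
  coh <- simulate_cohort(cfg)
  E <- simulate_expression(cfg, coh, clip_negative = FALSE)
  inex <- coh$inex_ratio
  ok <- is.finite(inex)
  expect_equal(unname(E[ok, "up"]), 50 + 20 * inex[ok], tolerance = 1e-12)
  expect_equal(unname(cor(E[ok, "up"], inex[ok])), 1, tolerance = 1e-12)
  expect_equal(unname(cor(E[ok, "dn"], inex[ok])), -1, tolerance = 1e-12)
})

test_that("null genes show only sampling-level correlation across seeds", {
  panel <- data.frame(gene_id = "nil", baseline = 50, slope = 0,
                      noise_sd = 10)
  rs <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, gene_panel = panel)
    coh <- simulate_cohort(cfg)
    E <- simulate_expression(cfg, coh)
    ok <- is.finite(coh$inex_ratio)
    abs(cor(E[ok, "nil"], coh$inex_ratio[ok]))
  }, numeric(1))
  n <- 100  # cohort size per seed
  expect_lt(mean(rs), 2 / sqrt(n))
})

test_that("negative expression draws are clipped at zero by default", {
  panel <- data.frame(gene_id = "lowg", baseline = 1, slope = 0,
                      noise_sd = 20)
  cfg <- sim_config(seed = 23, gene_panel = panel)
  coh <- simulate_cohort(cfg)
  expect_true(min(simulate_expression(cfg, coh)) >= 0)
  expect_lt(min(simulate_expression(cfg, coh, clip_negative = FALSE)), 0)
})

test_that("planted sequences carry exactly the planned motifs and GU runs", {
  cfg <- sim_config(seed = 29)
  sim <- simulate_sequences(cfg)
  s <- sim$sequences[["KITsyn_flank"]]
  truth <- sim$truth
  tr <- scan_sequence(s, sequence_id = "KITsyn_flank")
  for (i in which(truth$element != "gu_run")) {
    lo <- truth$start[i]; hi <- truth$start[i] + truth$length[i]
    covering <- tr[tr$window_start <= lo &
                     tr$window_start + 45 >= hi, ]
    expect_identical(max(covering$raw_score), truth$expected_raw[i],
                     info = truth$element[i])
  }
  expect_identical(max(tr$raw_score), max(truth$expected_raw, na.rm = TRUE))
  runs <- find_gu_runs(s)
  gu <- truth[truth$element == "gu_run", ]
  expect_identical(runs$start, gu$start)
  expect_identical(runs$length, gu$length)
})

test_that("a plan without YCAY elements scans to an all-zero track", {
  plan <- data.frame(sequence_id = "bare", element = "gu_run",
                     start = 10L, param = 4L)
  # plan with no YCAY elements: track must be all zero
  sim <- simulate_sequences(sim_config(seed = 31, motif_plan = plan))
  tr <- scan_sequence(sim$sequences[["bare"]])
  expect_true(all(tr$raw_score == 0L))
})

test_that("overlapping planted elements are rejected", {
  plan <- data.frame(sequence_id = "s", element = c("triple_tight",
                                                    "triple_mixed"),
                     start = c(60L, 65L), param = NA_integer_)
  expect_error(simulate_sequences(sim_config(motif_plan = plan)),
               "overlap")
})

test_that("sequence fixtures round-trip through FASTA and truth TSV", {
  dir <- tempfile()
  cfg <- sim_config(seed = 37)
  sim <- simulate_sequences(cfg, dir = dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
  expect_identical(as.character(fa[["KITsyn_flank"]]),
                   sim$sequences[["KITsyn_flank"]])
  truth <- data.table::fread(file.path(dir, "motif_truth.tsv"))
  expect_identical(nrow(truth), nrow(sim$truth))
})
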