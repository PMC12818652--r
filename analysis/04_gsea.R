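#!/usr/bin/env Rscript
# Stage 4: rank panel genes by Pearson correlation of expression with the
# in-ex ratio and run pre-ranked GSEA (1000 gene-label permutations,
# seed 1111) on the planted gene sets.
suppressPackageStartupMessages(library(inexr))

seed <- 101L
cfg <- sim_config(seed = seed)
records <- simulate_cohort(cfg)          # same seed: same cohort as stage 1
expr <- simulate_expression(cfg, records)
cohort <- data.table::fread("results/inex/cohort.tsv", skip = "#")

sets <- c(cns_like_set(cfg),
          list(DOWN_like = cfg$gene_panel$gene_id[cfg$gene_panel$slope < 0]))
g <- run_gsea(cohort, expr, sets, out_dir = "results/gsea")

message("top of the ranked list:")
print(head(g$ranked, 5))
message("enrichment results:")
print(g$results)
message("outputs written under results/gsea/")
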