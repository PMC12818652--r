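#!/usr/bin/env Rscript
# Stage 3: compare per-tissue in-ex distributions — pairwise W1 distances,
# complete-linkage dendrogram, and the CNS vs non-CNS exact Wilcoxon
# rank-sum test with effect size r = |Z|/sqrt(N).
suppressPackageStartupMessages(library(inexr))

cohort <- data.table::fread("results/inex/cohort.tsv", skip = "#")

cmp <- run_compare(cohort, out_dir = "results/compare")

message("Wasserstein distance matrix (W1 on raw ratios):")
print(round(cmp$distance_matrix, 3))
message("dendrogram: ", cmp$newick)
message(sprintf("CNS vs non-CNS: p = %.3g, Z = %.3f, r = %.3f (N = %d)",
                cmp$test$p_value, cmp$test$z_statistic,
                cmp$test$effect_size_r, cmp$test$n))
message("outputs written under results/compare/")
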