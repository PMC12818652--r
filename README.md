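# inexr — alternative 5′ splice-donor usage analysis via the in-ex ratio

Many genes carry two alternative 5′ splice donor sites a few codons apart
that feed a single shared acceptor. The best-studied case is *KIT*, where
two GU donors 12 nt apart toggle a four-residue juxtamembrane segment
(GN[N/S]K) in the c-KIT receptor: reads spanning the downstream-donor
junction (SDS2→SAS) support **inclusion** (GN[N/S]K+), reads spanning the
upstream-donor junction (SDS1→SAS) support **exclusion** (GN[N/S]K−).
`inexr` is for transcriptomicists who want to quantify such an event from
splice-junction evidence (STAR `SJ.out.tab` files) across a tissue cohort
and ask where, and how strongly, the isoform balance shifts.

The central statistic is the **in-ex ratio** of a sample,

```
in-ex ratio = ([SDS2&SAS] − [SDS1&SAS]) / ([SDS2&SAS] + [SDS1&SAS]),
```

which ranges from −1 (all exclusion) to +1 (all inclusion) and is
undefined when no junction read is observed. Samples are filtered to
target-gene expression ≥ 1 TPM and ≥ 3 junction-spanning reads. On the
filtered cohort the package compares per-tissue ratio distributions with

* the exact **1-Wasserstein distance** `W1(F, G) = ∫|F⁻¹(t) − G⁻¹(t)| dt`
  between empirical distributions (quantile-function merge, no binning),
* **complete-linkage hierarchical clustering** of the W1 matrix with a
  deterministic lexicographic tie-break, exported as Newick,
* the **exact Wilcoxon rank-sum test** (shift algorithm over doubled
  midranks, so ties are exact too) with the rank-based effect size
  `r = |Z|/√N` from the tie-corrected standardised rank sum,
* correlation-ranked **pre-ranked GSEA**: genes ranked by Pearson
  correlation of TPM with the in-ex ratio, weighted KS running-sum
  enrichment score, gene-label permutations, NES by same-sign
  normalisation, BH adjustment (defaults: set sizes 20–500, cutoff 0.01,
  seed 1111),
* **NOVA2 YCAY-cluster scoring**: 45-nt windows advancing 1 nt, pattern
  scores {0, 1, 2, 4, 8} for YCAY pairs/triples by gap length, log10
  transform with the 0.6 conservation threshold, plus detection of
  GU-rich stretches (runs of ≥ 4 consecutive G/U), and
* a **synthetic-data generator** (binomial inclusion counts with
  CNS-shifted probabilities over negative-binomial depth, linear-model
  expression panels, sequences with planted motif clusters and ground
  truth) so the entire pipeline is testable without downloads.

## Worked example

The numbered drivers under `analysis/` run the whole pipeline on synthetic
data (seed 101): `01_simulate.R` → `02_inex.R` → `03_compare.R` →
`04_gsea.R` → `05_motifscan.R`, writing their tables under `results/`.
Stage 3 prints, for a 100-sample cohort (two CNS tissues at inclusion
probability 0.7, two peripheral at 0.2):

```
Wasserstein distance matrix (W1 on raw ratios):
          forebrain heart hindbrain liver
forebrain     0.000 0.949     0.031 0.992
heart         0.949 0.000     0.966 0.049
hindbrain     0.031 0.966     0.000 1.010
liver         0.992 0.049     1.010 0.000
CNS vs non-CNS: p = 1.98e-29, Z = 8.617, r = 0.862 (N = 100)
```

CNS tissues sit ~1.0 W1 units from peripheral ones but only ~0.03 from
each other, so the dendrogram's first branch separates CNS from the rest,
and the Wilcoxon effect size r = 0.862 quantifies the inclusion shift.
Stage 4 then recovers the planted expression structure — the set of genes
rising with the in-ex ratio gets NES +3.14 (adjusted p ≈ 0.002), the
falling set NES −3.11 — and stage 5 finds the planted triple-YCAY cluster
as a window of raw score 8 (log10 = 0.903, above the 0.6 threshold) and
the planted 6-nt GU run.

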