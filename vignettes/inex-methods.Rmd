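---
title: "Quantifying alternative 5' donor usage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative 5' donor usage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inexr)
library(data.table)
```

`inexr` quantifies the balance between two alternative 5′ splice donor
sites feeding one shared acceptor — the geometry of the *KIT* GN[N/S]K+/−
isoform pair, where the donors sit 12 nt (four codons) apart — and
compares that balance across a tissue cohort. This vignette explains the
statistical machinery, the tunable parameters, and the choices made where
the design was genuinely open. It states no result that the package's
tests and scripts do not themselves compute.

## The event model and junction classification

An event is three coordinates on one chromosome: the upstream (exclusion)
donor SDS1, the downstream (inclusion) donor SDS2, and the shared
acceptor SAS. We adopt the STAR `SJ.out.tab` convention throughout —
1-based coordinates, `intron_start` the first intronic base,
`intron_end` the last — because junction tables are the only stable
interface between aligners and this analysis; BED-style half-open input
is converted on read by a single function pair (`to_bed0()` /
`from_bed0()`). On `-`-strand genes the donor-side boundary of a junction
record is `intron_end`, and "downstream" means a smaller genomic
coordinate; `splice_site_spec()` validates the ordering per strand.

A junction record is INCLUSION if its donor boundary equals SDS2 and its
acceptor boundary equals SAS, EXCLUSION for SDS1/SAS, OTHER in every
other case (including chromosome mismatch, which is ordinary data, not an
error). Records with undefined strand are classified by coordinates
alone — the event's strand already fixes which boundary is the donor.
By default only uniquely-mapping reads (STAR column 7) are counted;
`count_mode = "unique_plus_multi"` adds multimappers, exposed because
alignment pipelines differ in whether multimapping junction reads are
trustworthy, and the upstream aligner settings cannot be recovered from a
junction table.

The in-ex ratio is `(inc − exc)/(inc + exc)`. With both counts zero the
ratio is undefined and reported as `NA`, never 0 — an unobserved event is
not evidence of balance — and such samples are removed anyway by the
read-depth filter below.

## Sample filters

`filter_samples()` keeps samples with target-gene expression
`gene_tpm >= 1` and `inclusion + exclusion >= 3` junction-spanning reads,
both thresholds inclusive. One TPM is the conventional floor for calling
a gene expressed; three reads is the minimum at which a ratio is more
than a coin flip. Filtering is idempotent and reports per-tissue
retention so cohort attrition is visible.

## Comparing tissue distributions

**Wasserstein distance.** Tissue-level ratio distributions are compared
with the exact 1-Wasserstein distance on the *raw* per-sample ratios.
`wasserstein1d()` merges the cumulative-probability breakpoints of the
two empirical CDFs and integrates `|Q_x(t) − Q_y(t)|` over the resulting
segments; no binning, no Monte Carlo. Histogram bins (`bin_width = 0.1`
over [−1, 1], unit-area normalised per group) are presentation only.
The tests verify the implementation against an independent
northwest-corner solution of the discrete transport problem, which is
provably optimal for a convex cost in one dimension.

**Clustering.** The W1 matrix is clustered with complete linkage.
We implement the agglomeration directly rather than delegating to
`stats::hclust` so that ties merge deterministically — among all pairs at
the minimal distance, the pair with the lexicographically smallest member
labels merges first — making dendrograms reproducible regardless of input
order; `hclust` serves as an independent cross-check on generic (tie-free)
matrices in the tests. Trees are exported as Newick via `ape`.

**Wilcoxon rank-sum with effect size.** The CNS vs non-CNS contrast uses
a two-sided rank-sum test that is exact *including ties*: midranks are
doubled to make the scores integral and the full permutation null of the
rank sum is built by the shift (generating-function) algorithm; the
two-sided p doubles the smaller tail, which is exact because the midrank
multiset is symmetric about (N+1)/2. The reported effect size is
`r = |Z|/√N` with Z standardised by the tie-corrected permutation mean
and variance — the standard companion definition for rank tests, adopted
here because it is the magnitude that published rank-sum effect sizes
report. `auto` mode (default) switches to the tie-corrected normal
approximation above `exact_max_n = 200` pooled observations: the exact
dynamic program is O(N·n₁·ΣR) and beyond a few hundred observations the
approximation agrees to many digits while the exact tail underflows
double precision anyway.

**CNS assignment** is a deterministic lookup from tissue category
(brain/forebrain/midbrain/hindbrain/cerebellum/spinal cord/neural
tube/CNS), overridable per call, since category vocabularies differ
between metadata sources.

## Correlation-ranked enrichment

Genes are ranked by the Pearson correlation of their TPM with the in-ex
ratio across samples (at least three shared samples required).
Zero-variance genes score 0 and are flagged rather than dropped, so the
ranked universe is stable; ties break lexicographically by gene id.

The enrichment score is the weighted KS running sum: at member positions
the sum gains `|score|^p / Σ|member scores|^p` (default `p = 1`), at
non-member positions it loses `1/(N − N_members)`, and ES is the extremum
of largest magnitude (positive wins exact-magnitude ties). With `p = 0`
this is the classic KS statistic on ranks, a reduction the tests check
directly; the implementation is also cross-checked against
`fgsea::calcGseaStat`.

Because only a ranked list enters, the permutation scheme is gene-label
permutation: member positions are redrawn uniformly `n_perm = 1000` times
under a caller-supplied seed (default 1111). NES divides ES by the mean
|ES| of same-sign permutations (the original GSEA normalisation) and the
p-value is the same-sign permutation tail with add-one smoothing,
`(1 + #{|ES_perm| ≥ |ES|, same sign}) / (1 + #{same sign})`. We verified
on simulated nulls that this conditional estimator is approximately
uniform under random sets (a tail over all permutations regardless of
sign is visibly anti-conservative, compressing null p-values by roughly
the same-sign fraction). Its floor is `1/(1 + #same-sign)`, at best
`1/(n_perm + 1)`. BH adjustment runs across sets; `significant` flags
`p_adjusted < 0.01`. Set-size filtering (20–500, inclusive, measured on
the intersection with the ranked universe) happens before scoring.
The published analysis fed "top and bottom" genes without stating a
cutoff; the default here is the full ranked list, with an optional
`top_bottom_k` truncation for users who want the published behaviour at a
cutoff of their choosing.

## YCAY cluster scoring and GU runs

The NOVA-family motif YCAY (`[C/U]CA[C/U]`, T≡U) is matched greedily
left-to-right without overlap. A 45-nt window advancing 1 nt is scored by
grouping its motifs greedily from the left, gaps measured between one
motif's end and the next motif's start: triples with gaps (≤2, ≤2) score
8, mixed (≤2 with 3–6, either order) score 4, pairs score 2 (gap ≤2),
1 (gap 3–6) or 0 (gap ≥7). Groups are disjoint — a tight triple scores 8,
not 8 plus its trailing pair — otherwise the printed pattern scores could
not be reproduced. Each window is scored independently (greedy matching
restarts inside the window), and `log_score = log10(raw)` for raw ≥ 1,
else 0, keeping tracks plottable; the 0.6 display threshold then
separates raw ≥ 4 (a triple, or two pair groups) from raw ≤ 3.

Two cases are underdetermined by the published pattern table and resolved
explicitly here. First, a pair at gap ≥ 7 is not one cluster, so the scan
advances past only the *left* motif and the right motif stays available
to anchor a later group (consuming both would silently zero a tight pair
following a lone distant motif). Second, a triple with gaps (3–6, 3–6)
has no printed score; it is scored as its leading 3–6 pair (1) with the
third motif carried forward, and the event is reported when
`options(inexr.verbose = TRUE)`. Scanning is strand-explicit: the
provided (sense) string is scanned as-is, and the tests assert that the
reverse complement does not simply reverse the track.

GU-rich stretches are maximal runs of ≥ 4 consecutive G/U, reported in
0-based half-open coordinates (all BED/bedGraph output is half-open; all
SJ-dialect I/O is 1-based inclusive).

## The synthetic-data generator

`sim_config()` defines the simulated study. Defaults: four tissues — two
CNS at inclusion probability 0.7, two peripheral at 0.2, 25 samples each
— with per-sample junction depth negative-binomial (mean 100, dispersion
10) to emulate uneven RNA-seq coverage, inclusion reads binomial in the
tissue probability, and target-gene TPM gamma (mean 30, sd 15) so nearly
all samples clear the 1-TPM filter at realistic expression. The gene
panel is 60 genes: 20 rising with the ratio (slope +30 TPM per ratio
unit), 20 falling, 20 null, all with baseline 50 and noise sd 10 —
correlations around 0.8 for the informative genes, comparable to a clean
tissue-panel signal. The sequence plan plants one tight YCAY triple, one
mixed triple, one tight-pair-plus-distant-motif cluster and one 6-nt GU
run on a background (`AAGC` repeats) that is provably YCAY-free and
GU-run-free; planted elements are spaced so no 45-nt window spans two,
and generation fails loudly if planting ever creates a stray motif.
All randomness flows from the single seed; repeated runs are
byte-identical, and generated SJ files include decoy junctions so the
OTHER classification path is always exercised.

What the generator does *not* emulate: library-size and GC biases,
correlated gene-gene noise, multimapping ambiguity, annotation errors,
and between-tissue depth differences. Passing the end-to-end tests
therefore shows the statistics recover planted structure under clean
sampling noise — it does not certify behaviour on real cohorts, where the
filters and the rank-based statistics are the main defences.

## Numerical choices and degenerate inputs

* Exact Wilcoxon counts are doubles; they remain exact to well beyond
  the N = 200 exact-mode ceiling (C(200,100) ≈ 9·10⁵⁸ « 2⁵³-precision
  relative error), and p-values are ratios, so representation error is
  negligible.
* A fully tied pooled sample has zero rank variance; the test returns
  p = 1, Z = 0, r = 0 rather than dividing by zero.
* `wasserstein1d` guards quantile indexing with a 1e-9 slack against
  floating breakpoints; the distance-matrix invariants (symmetry, zero
  diagonal, triangle inequality) are asserted to 1e-9 in tests.
* Enrichment on a set whose member scores are all zero falls back to
  equal member weights instead of 0/0.
* Count tables re-read from TSV recompute the ratio from the integer
  counts, so round-trips are bit-exact regardless of decimal rendering.
* Output tables carry a `# inexr <version>; # params: ...` provenance
  header and never a timestamp, so repeated runs are byte-identical.

## Problem sizes

The shipped tests and drivers run the cohort pipeline at 100 samples ×
~100 reads, parameter-recovery sweeps over 100 seeds, 500-instance
transport-oracle checks, 1000 random 45-mers against the motif oracle,
and GSEA at 1000 permutations over a 60-gene panel — sizes chosen so the
whole suite completes in well under a minute while leaving the binomial
and permutation approximations nothing to hide behind.

## Known limitations

* The event must be user-specified; the package does not discover novel
  alternative-donor events, and the packaged `gnnk_event()` is a
  synthetic stand-in with the correct 12-nt geometry, not reference
  coordinates.
* Exact Wilcoxon beyond a few hundred observations is deliberately
  unsupported (auto-fallback); p-values at that scale are below double
  precision regardless.
* GSEA p-values come from gene-label permutation and inherit its
  assumption that gene scores are exchangeable under the null;
  correlated gene panels will be anti-conservative, as for any
  pre-ranked GSEA.
* Per-species GO-term results of the original tissue-wide study depend
  on external annotation versions and full-size cohorts and are out of
  scope; the package reproduces the machinery, and its acceptance checks
  against the published per-species effect sizes require the original
  per-sample supplementary table, which cannot be redistributed here.
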