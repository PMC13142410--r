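# cooctag

Tools for dual-target, combinatorially indexed chromatin profiling — assays
in which two barcoded transposases, directed at two different chromatin
targets, tagment the same cells. A fragment whose two adapter barcodes come
from the same transposase plate reports one target (mono-occupancy); a
fragment with mixed barcodes shows both targets flanking the same DNA
molecule (co-occupancy). For H3K27me3 paired with H3K4 methylation, the
co-occupancy stream is direct, same-molecule evidence of bivalent chromatin.

The package is aimed at analysts of such experiments and implements the
assay-specific computation between sequencing and biology:

- **Demultiplexing** of the dual 8×12 plate scheme (s5 barcodes 1–8 / 9–16,
  s7 barcodes 1–12 / 13–24, nanowell p5/p7 indices) into `target1`,
  `target2`, `co1`, `co2` streams, with cell barcodes rewritten to
  `well + p5 + p7` so all four streams from one cell share one barcode.
- **Fragment processing**: BEDPE → deduplicated fragment BED, coverage-scaled
  BedGraph tracks (`1e10 / total coverage`, or a shared anchor-mark factor),
  per-cluster pseudobulks (`1e4 / n_cells`).
- **Chromatin-state calling**: a two-component Gaussian mixture on
  `log10(score + 0.1)` per mark, thresholded at the intersection of the
  weighted component densities

  `w1 N(x; mu1, sigma1) = w2 N(x; mu2, sigma2)`,

  then per gene and cluster: *bivalent* if H3K4, H3K27me3 and co-occupancy
  all exceed their thresholds; *active* (H3K4 only), *repressed* (H3K27me3
  only), *unmarked* (neither), *other* (both marks without co-occupancy
  support); consensus = the modal state across the three H3K4 marker pairs
  when it appears at least twice. Fate maps summarize root-to-lineage state
  transitions.
- **Embedding QC**: >250-fragment retention, doublet-score cluster filtering,
  k-means (100 groups) genotype-doublet neighborhood removal at the >15%
  rule, the pair-closeness fidelity score `S_pair` (fraction of up to 5,000
  sampled cells closer than the matched partner, averaged over the pair),
  cross-modality cluster overlap matrices, marker-based annotation scores.
- **Pseudotime utilities**: rank-scaled pseudotime (0–100), median-z gene
  module scores, loess-smoothed profiles, and half-max activation times
  (earliest pseudotime where the min–max-rescaled smoothed profile
  exceeds 0.5).
- **Cis-regulatory elements**: gene domains bounded by nearest
  non-overlapping neighbors, greedy 100-bp summit collapsing, 200-bp
  summit-centered windows merged across lineages, CPM quantification,
  5%/95% outlier filtering, column-standardized and mark-block-normalized
  PCA → kNN → Leiden element clustering, promoter fractions (TSS ± 2 kb),
  `log2((O+0.5)/(E+0.5))` domain enrichment with softmax weights, Fisher
  exact co-occurrence networks with Haldane log2 odds ratios and BH
  correction, and Mann–Whitney per-domain comparisons.

A seeded synthetic-data module (`sim_config()`, `simulate_reads()`,
`simulate_genescores()`, `simulate_embedding()`, `simulate_summits()`)
generates every input with ground truth, so the entire pipeline is testable
offline. See the methods vignette
(`vignettes/cooccupancy-pipeline.Rmd`) for the models, parameter defaults and
design decisions.

## Worked example

Simulate a barcoded experiment, demultiplex it, and call chromatin states:

```r
library(cooctag)

scheme <- make_barcode_scheme(seed = 1)
cfg <- sim_config(seed = 1, n_cells = 100, barcode_error_rate = 0.02)
dir <- tempfile()
sim <- simulate_reads(cfg, scheme, n_reads = 10000, out_dir = dir)
res <- demultiplex(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                   file.path(dir, "I1.fastq"), file.path(dir, "I2.fastq"),
                   scheme)
res
#> demux_result: 10000 read pairs
#>   target1        3524 (35.24%)
#>   target2        3498 (34.98%)
#>   co1            1501 (15.01%)
#>   co2            1477 (14.77%)
#>   unassigned        0 (0.00%)
```

Every read lands in a stream despite the 2% barcode error rate: the
whitelists keep pairwise Hamming distance ≥ 3, so single substitutions are
uniquely corrected at the default `max_mismatch = 1`.

```r
gs <- simulate_genescores(sim_config(seed = 1, n_genes = 1000, n_clusters = 4))
st <- call_states(gs$k27, gs$k4, gs$co)
st$fits$k27
#> Two-component Gaussian mixture (log10(score + 0.1) scale)
#>   low : mu = -0.1845  sigma = 0.3632  w = 0.515
#>   high: mu = 1.4177  sigma = 0.4039  w = 0.485
#>   threshold = 0.5894   (n = 4000, converged in 29 iterations)
table(st$calls$consensus)
#>    active  bivalent      none     other repressed  unmarked
#>      1237       984         5        26       910       838
mean(st$calls$consensus == gs$truth$state)
#> [1] 0.97575
```

The fitted H3K27me3 mixture recovers the planted components (true means
−0.2 and 1.4, equal weights) and places the threshold at their density
intersection; the consensus calls recover 97.6% of the planted gene states.
The `none` and `other` columns are genes whose three marker pairs disagreed
or whose marks exceeded thresholds without co-occupancy support — both are
flags for exclusion downstream.

A thin command-line wrapper for shell pipelines is installed at
`inst/cli/cocotag.R`:

```sh
Rscript inst/cli/cocotag.R simulate-reads --seed 1 --n-cells 200 \
    --n-reads 10000 --out sim/
Rscript inst/cli/cocotag.R demux --r1 sim/R1.fastq --r2 sim/R2.fastq \
    --i1 sim/I1.fastq --i2 sim/I2.fastq --scheme sim/scheme.json --out demux/
```

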