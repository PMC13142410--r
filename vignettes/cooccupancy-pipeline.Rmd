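---
title: "Methods: dual-target co-occupancy chromatin profiling with cooctag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-target co-occupancy chromatin profiling with cooctag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooctag)
```

# The assay and the computational problem

In a dual-target tagmentation experiment, two antibody-directed transposases —
each loaded from its own 96-well plate of barcoded adapters — insert into
chromatin around two different targets (for example H3K27me3 and an H3K4
methylation mark). A sequenced fragment carries two adapter barcodes, one from
each insertion end. When both barcodes come from the same transposase's plate,
the fragment reports a single target (mono-occupancy); when the barcodes are
mixed, the two targets flanked the same DNA molecule, which is direct evidence
of co-occupancy — for H3K27me3 plus H3K4 methylation, bivalent chromatin.

The first plate carries s5 adapter barcodes 1–8 across its rows and s7
barcodes 1–12 across its columns; the second plate carries s5 9–16 and
s7 13–24 in the same grid. Nanowell (p5, p7) index barcodes added during PCR
complete the cell barcode. `cooctag` implements everything downstream of
sequencing that is specific to this design:

1. **demux** — route each read pair to `target1`, `target2`, `co1` or `co2`
   from its (s5, s7) combination, and rewrite the cell barcode as
   `well + p5 + p7` so that all four streams from one physical cell share one
   barcode (`demultiplex()`, `assign_stream()`, `well_id()`).
2. **fragments** — BEDPE to deduplicated fragment BED, coverage-scaled
   BedGraph tracks, per-cluster pseudobulks
   (`bedpe_to_fragments()`, `deduplicate()`, `make_bedgraph()`,
   `pseudobulk()`).
3. **states** — two-component Gaussian-mixture thresholding of pseudobulk
   gene scores and five-way chromatin-state calls with a 2-of-3 consensus
   (`fit_mixture()`, `classify_states()`, `consensus_state()`,
   `transition_table()`).
4. **embedqc** — retention filters, doublet-neighborhood removal, the
   pair-closeness statistic, cross-modality cluster overlap and marker-based
   annotation scoring (`min_fragment_filter()`, `genotype_doublet_filter()`,
   `s_pair()`, `cluster_overlap_matrix()`, `annotation_score()`).
5. **trajectory** — rank-scaled pseudotime, gene-module scores and half-max
   activation timing (`scale_pseudotime()`, `module_score()`,
   `activation_time()`).
6. **cre** — gene domains, summit merging, fixed-width element windows, CPM
   quantification, element clustering and enrichment / co-occurrence /
   per-domain statistics (`gene_domains()`, `merge_summits()`,
   `quantify_elements()`, `cluster_elements()`, `domain_enrichment()`,
   `cooccurrence()`, `domain_element_stats()`).

Peak calling, alignment, LSI/Harmony embedding, genotype demultiplexing and
doublet scoring are upstream tools whose outputs this package consumes; they
are deliberately out of scope.

# Demultiplexing model

An observed barcode is matched against its whitelist by Hamming distance: the
unique entry within `max_mismatch` (default 1) wins; no hit, or two or more
entries tied at the minimal distance, leaves the read unassigned. Whitelists
are validated at load: within each whitelist read at one position (the 16 s5
sequences, the 24 s7 sequences, each nanowell set) all sequences must be
unique with pairwise Hamming distance greater than `2 * max_mismatch`, which
makes single-substitution errors uniquely correctable and ambiguity
impossible at the default tolerance. The positions of the barcodes inside the
two index reads are configuration (`i1_layout`, `i2_layout`), not convention,
since instrument recipes differ.

Stream assignment and the well rewrite are pure functions of the barcode
indices: `(s5 ≤ 8, s7 ≤ 12) → target1`, `(s5 > 8, s7 > 12) → target2`, mixed
combinations to `co1`/`co2`; row `A–H` is the s5 rank on either plate, column
`1–12` the s7 rank. The four combinations of one well therefore collapse to
one well ID — the property that lets the cell barcode be shared across all
four streams — and this is tested exhaustively over all 8 × 12 × 4
combinations. The two co-occupancy files are kept separate so that which
paired end belongs to which target is preserved; concatenating them gives the
combined co-occupancy set most analyses use.

# Fragment processing and track scaling

Fragments are 0-based half-open intervals spanning both mates; pairs on
different chromosomes, and fragments longer than the insert-size cap
(default 1000 bp, the aligner's maximum), are dropped and counted.
Single-cell deduplication keeps one fragment per
`(chrom, start, end, cell)` — biological duplicates within one cell are
vanishingly unlikely — while bulk data retains duplicates.

Tracks are scaled by `1e10 / total coverage` (summed fragment length). For
paired-sample comparisons, the same formula computed on an anchor mark
(H3K27ac in the motivating design) is applied to *all* tracks of the sample,
so mono- and co-occupancy depths stay mutually comparable.
Per-cluster pseudobulk tracks use `1e4 / n_cells` instead. BedGraph emission
is fragment pileup (not read ends) as maximal constant-value intervals at
fixed decimal precision (default 5) for byte-stable output; mass conservation
(`sum(value × width) = factor × summed fragment length`) is asserted in the
tests against a per-base pileup oracle. BigWig conversion is left to
`bedGraphToBigWig`; BedGraph is the canonical text artifact.

# Chromatin-state model

Pseudobulk gene scores for each mark are transformed to `log10(score + 0.1)`
and fitted with a two-component Gaussian mixture. The implementation is a
plain EM with deterministic initialization (split at the median), tolerance
`1e-8` on the log-likelihood, at most 500 iterations — so fits are exactly
reproducible and invariant to input order. The classification threshold is
the intersection of the two weighted component densities, i.e. the point of
equal likelihood; with unequal variances this is a quadratic with the
relevant root constrained to lie between the means, and with equal variances
it reduces to `(mu1 + mu2)/2 + sigma^2 log(w1/w2)/(mu2 − mu1)`.

Degenerate inputs are handled without aborting a multi-mark run: when a
single Gaussian explains the data at least as well (BIC comparison), when the
components are closer than half the larger standard deviation, or when no
intersection exists between the means, the threshold falls back to the
midpoint of the means and the fit is flagged
(`degenerate` / `threshold_fallback`).

States are assigned per gene, cluster and marker pair with strict
inequalities ("exceeds" means `>`; exact ties at the threshold fall below):
**bivalent** when the H3K4 mark, H3K27me3 *and* the pair's co-occupancy
signal all exceed their thresholds; **active** when H3K4 is above and
H3K27me3 below; **repressed** for the reverse; **unmarked** when both are
below; and **other** for the remaining combination (both marks above without
co-occupancy support). The consensus over the three marker pairs
(H3K27me3 with H3K4me1/me2/me3) is the modal state when it appears at least
twice, else `none`.

Two points the procedure leaves open were resolved as follows. Thresholds are
fitted per mark on genes pooled across clusters (one threshold per mark),
with per-cluster fitting available via `per_cluster = TRUE`; pooling is the
default because cluster-level score distributions share the same mixture
structure and pooling stabilizes the fit for small clusters. And genes
labelled "other" vote in the consensus like any other label; since "other"
marks an inconsistent call, a 2-of-3 "other" consensus is itself useful as a
flag for exclusion, which is how such genes are treated downstream.

`transition_table()` summarizes root-to-lineage fate: per-lineage
root-state × downstream-state counts, the fraction of genes per root state
that reach "active" in at least one lineage, and how lineage-specific those
activations are (active in exactly 1, 2, ... lineages).

# Embedding quality control

The retention filter keeps a cell when any of its three modalities (two
mono-occupancy, one combined co-occupancy) has strictly more than 250
fragments. Doublet handling is two-staged. Cluster-level: cells with doublet
scores above a chosen threshold are putative doublets, and clusters whose
putative-doublet fraction exceeds a chosen fraction are dropped entirely.
Neighborhood-level (for genotype-mixed designs): cells are partitioned into
100 groups by seeded k-means in the batch-corrected embedding (Lloyd
iterations, 10 restarts), and any group with more than 15% genotype-labelled
doublets is removed from *all* modalities — set equality of the removed cells
across modalities is asserted in the tests. Both boundaries are strict
inequalities and both are exposed as arguments.

The pair-closeness statistic `S_pair` quantifies embedding fidelity from
matched same-cell profile pairs: for each member, the fraction of up to 5,000
sampled other cells (sampling seeded, without replacement, excluding the pair
itself; all cells when fewer are available) that lie closer to it than its
true partner, averaged over the two members. The average is taken over the
two pair members (one fraction each), a reading documented here because the
procedure could also be read as averaging over resamples; the per-member
scores are returned alongside so either summary can be formed. Coincident
partners give exactly 0, unrelated pairs 0.5 in expectation — both are
asserted, the latter at ±0.05 over 1,000 simulated cells.

Annotation scoring z-scales each reference gene across cell types
(zero-variance rows are set to 0 rather than propagating NaN) and averages
the scaled values over each cluster's marker genes; markers absent from the
reference are dropped and reported.

# Pseudotime utilities

Pseudotime is the cell rank along a supplied trajectory scaled to
`[0, 100]` (`100 (rank − 1)/(n − 1)`, mean ranks at ties; a single cell maps
to 0). Gene-module scores are per-cell medians of per-gene z-scores.
Profiles are smoothed with degree-2 loess at span 0.75 — the smoother's
default, used for activation timing; the figure-styling spans
(0.3/0.15/0.7) used for individual plots are a plotting concern, and the
span is exposed as an argument throughout.
Fitted values are clamped at 0, min–max rescaled to `[0, 1]`, and the
activation time is the earliest *observed* pseudotime whose rescaled value
strictly exceeds 0.5 (no interpolation between cells). One wording ambiguity
is resolved as min–max rescaling: the procedure says "subtracting the
minimum and dividing by the range", which is min–max normalization even
though a z-score is mentioned in passing; min–max is also what makes the
result invariant under positive affine transforms of the raw scores, a
property the tests assert. Flat profiles (zero range up to roundoff) have no
defined activation time and return `NA`.

# Cis-regulatory element classification

**Gene domains.** Transcript records are filtered to protein-coding entries,
collapsed per gene to the union span, and each gene's domain runs from the
end of its nearest upstream non-overlapping gene to the start of its nearest
downstream non-overlapping gene, with chromosome-edge genes bounded by the
minimum/maximum annotated coordinate. The scan is validated against a
brute-force nearest-neighbor oracle on random layouts.

**Summit processing.** Summits within 100 bp on the same chromosome are
collapsed by a greedy sorted sweep that keeps the higher-scoring summit
(score ties keep the earlier). Comparisons are anchored to the last
*retained* summit — not chained through raw positions — the simplest reading
of a greedy sweep; the retained summit's position moves to the
higher-scoring member when it is replaced. Retained summits become
200-bp windows clipped at chromosome edges. Per-lineage window sets are
concatenated and merged; merged intervals wider than 200 bp (lineages placed
their summits differently) are re-centered on the highest-scoring original
summit overlapping the interval.

**Quantification and clustering.** Fragments overlapping a window by
at least 1 bp (half-open arithmetic) are counted per (cluster, mark) fragment
set and scaled to counts per million of that set's total. Elements in the
strict 5%/95% tails of the cumulative (row-sum) signal are removed
(linear-interpolation percentiles, so a fully tied matrix is retained). The
matrix is column-standardized (zero-variance columns set to 0), each
histone-mark column block rescaled to the median block Frobenius norm, then
PCA (16 components by default, lowered with a warning on small matrices), a
30-nearest-neighbor graph with inverse-Euclidean edge weights (distances
floored at `1e-12`), and seeded Leiden clustering at resolution 4
(`igraph::cluster_leiden` with the modularity objective, igraph's equivalent
of the resolution-scaled configuration-model partition). Labels are
canonicalized by descending class size. A 2-D UMAP (40 neighbors, min-dist
0.25, Euclidean) is attached for reporting only. A second clustering round at
resolution 0.5 refines selected classes, overwriting only the selected rows'
labels. Resolution 4 is the default for genome-scale element matrices (tens
of thousands of windows); the synthetic three-class fixtures used in the
tests are two orders of magnitude smaller, and are clustered at resolution
0.5, chosen from the fixture's blob structure.

**Statistics.** Promoter fractions use TSS ± 2 kb windows. Element-class ×
gene-domain-group enrichment is `log2((O + 0.5)/(E + 0.5))` with expected
counts `N_e × f_g` from the genome-wide overlap fraction; the pseudocount is
added to both observed and expected (the stabilization is symmetric that
way), and row-wise softmax weights present each element class's domain
preferences summing to one. Domain groups must be gene-disjoint; violations
are an error naming the genes. Co-occurrence across gene domains uses
two-sided Fisher exact tests on the per-pair 2×2 tables
(`stats::fisher.test`, which sums hypergeometric probabilities not exceeding
the observed table's — verified against full enumeration in the tests) with
Haldane-stabilized log2 odds ratios (0.5 in every cell) and
Benjamini–Hochberg adjustment; network edges default to significant positive
associations, thinned to the 50 largest |log2 OR| with degree-1 pruning
(both exposed — the backbone sizes are presentation choices). Per-domain
count and max-signal comparisons use Wilcoxon rank-sum tests
(`stats::wilcox.test` defaults: exact for small tie-free samples, normal
approximation with continuity and tie correction otherwise) with BH
adjustment across comparisons.

# What the synthetic data emulates — and what it does not

The generator module produces every input the pipeline needs, with ground
truth, from a `sim_config()`:

- `simulate_reads()` — reads over the dual-plate scheme with per-barcode
  corruption: each of the four barcodes is independently corrupted with
  probability `barcode_error_rate` by exactly one substitution. Under this
  model the corrupted-barcode fraction equals the configured rate, every
  corrupted barcode is recoverable at `max_mismatch = 1` (whitelist distance
  ≥ 3), and the assignment rate at `max_mismatch = 0` is `(1 − rate)^4` —
  all three are asserted against binomial confidence intervals.
- `simulate_genescores()` — planted states drawn from the configured state
  fractions; mark scores drawn from the high/low mixture component dictated
  by the state rule, as normals on the `log10(score + 0.1)` scale truncated
  at −1 (the domain boundary for nonnegative scores). Defaults
  `mu_low = −0.2`, `mu_high = 1.4`, `sigma = 0.4` place the components
  4 standard deviations apart — the regime in which mixture thresholding is
  expected to work — with the low component two standard deviations above
  the truncation boundary so the emulated mixture genuinely has that
  structure; raw-score magnitudes (~0.5 vs ~25) are typical of pseudobulk
  gene scores. State fractions default to
  active .30 / repressed .25 / bivalent .25 / unmarked .20.
- `simulate_embedding()` — Gaussian blobs around well-separated centroids
  (unit within-cluster spread, centroid scale 10), matched partners at a
  controllable displacement, and a planted doublet neighborhood at the
  midpoint of two centroids — mirroring how barcode-collision doublets
  project between their parent populations — with genotype-doublet labels at
  30% inside and 2% outside by default. The doublet-removal checks use 5,000
  background plus 300 planted cells so that 100 k-means groups of ~50 cells
  make the 2% vs 30% contrast statistically unambiguous at the 15% rule.
- `simulate_summits()` — three planted element classes on a 10-Mb synthetic
  chromosome (~33 kb spacing): promoters (H3K4me3-high everywhere, at
  planted TSSs), enhancers (H3K4me1-high, strongest in a home lineage,
  distal to every TSS by construction), and Polycomb-repressed elements
  (H3K27me3-high), with per-lineage jittered summits and Poisson fragment
  counts over uniform background.

What passing these tests shows is that the *estimators* do what their
definitions say under the statistical structure they assume. What it does
not show: robustness to the things real chromatin data adds — overlapping
gene models and nested domains at real annotation density, copy-number and
accessibility biases in fragment counts, mixture components that are skewed
or heavy-tailed rather than Gaussian, batch structure in embeddings, or
doublets that are not neatly localized. Sequencing quality scores are
constant placeholders; no reference genome is simulated because everything
downstream of demultiplexing consumes fragments, not alignments.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 50,000 read
pairs for the demultiplexing round trip, 5,000 mixture draws, 2,000 genes ×
6 clusters for state recovery, 1,000 cells for the pair-closeness null,
5,300 cells for doublet-neighborhood removal, 1,000 random summit instances
against the exhaustive oracle, and ~300 planted elements for the full
element pipeline. Every stochastic step is seeded explicitly; generators are
pure functions of their configuration, and fits, k-means, Leiden and UMAP
all take explicit seeds.

# Known limitations

- The EM fits exactly two components; scores with three or more modes are
  thresholded at the dominant boundary only.
- `s_pair()` computes exact distances per member; for very large embeddings
  (hundreds of thousands of cells) a nearest-neighbor-indexed variant would
  be preferable.
- `knn_graph()` builds a dense distance matrix; element matrices beyond
  ~20,000 windows would need an approximate-neighbors backend.
- Gene-score computation, trajectory inference, imputation and motif
  enrichment are consumed as inputs, by design.
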