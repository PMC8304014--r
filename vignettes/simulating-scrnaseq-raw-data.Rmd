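---
title: "Simulating single-cell RNA-seq raw data from a known ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single-cell RNA-seq raw data from a known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrnasim)
```

## Why simulate raw reads rather than counts

Most scRNA-seq simulators emit a count matrix directly from a parametric
model. That skips everything between the molecule and the matrix: barcode
errors, UMI collisions, PCR amplification bias, sequencing errors, and the
quantification software's responses to all of them. scrnasim instead fixes a
*true* mRNA copy-number matrix and replays the laboratory process —
fragmentation, tagging, amplification, sequencing — so that any
quantification or clustering pipeline can be scored against a known answer,
with every distortion between truth and matrix attributable to a concrete,
tunable mechanism.

The pipeline has five stages, each a pure function of its inputs and a seed:

1. **Ground truth** (`synthesize_reference_panel()`, `fit_reference_panel()`,
   `sample_ground_truth()`): a *reference panel* holds, for every gene and
   every cell subcategory, an independent normal distribution of expression.
   Cells are drawn per subcategory from these normals and converted to
   integer copy numbers.
2. **Library building** (`build_library()`): every true mRNA copy becomes a
   *fragment* (a truncated transcript interval); fragments get a per-cell
   barcode and a per-molecule UMI; PCR amplification expands each fragment
   into a recorded number of molecules with recorded substitutions.
3. **Sequencing** (`sequence_library()`): molecules are drawn with
   replacement, weighted by copy number; reads are assembled
   (read 1 = barcode‖UMI, read 2 = cDNA) and corrupted by an error/quality
   profile.
4. **Quantification** (`quantify_reads()`): barcode demultiplexing with
   Hamming-1 rescue, gene assignment, directional UMI deduplication.
5. **Evaluation** (`annotate_and_score()`, `run_benchmark()`): clusterings
   are scored by majority-label accuracy against the known labels.

## The ground-truth model

Real compendia of purified cell populations motivate the panel structure: a
hierarchy of major cell categories, each split into subcategories, with each
gene's expression inside a subcategory treated as an independent normal.
`fit_reference_panel()` estimates those normals from labelled expression
samples, using the per-gene sample mean and unbiased (n−1) variance whenever
a subcategory has at least three samples, and falling back to the gene's
overall mean and variance otherwise. A subcategory with zero matching
samples is an error — fabricating a cell type silently is never acceptable.

When no compendium is at hand, `synthesize_reference_panel()` builds a panel
from a hierarchical generative model: per-gene log-scale baselines
(`baseline_mean`, `baseline_sd`), log-normal perturbations per major
category (`major_effect_sd`) and per subcategory (`sub_effect_sd`), and
disjoint *marker genes* per subcategory. A marker's mean is set to
`marker_fold` times the gene's largest mean in any other subcategory, so
markers are discriminative by construction rather than by luck. Variance
scales with the squared mean (`noise_var_scale`, a squared coefficient of
variation) plus a floor of 0.25 so no gene is deterministic.

Defaults — 500 genes, 4 major × 3 subcategories, 5 markers per
subcategory at fold 4, baseline mean 1.0 on the log scale — were chosen once
so that major categories separate easily and subcategories only marginally.
That is the interesting regime: it reproduces the characteristic gap between
major- and sub-level clustering accuracy and leaves room for depth and
algorithm choices to matter.

Normal draws become copy numbers by rounding to the nearest integer and
clipping negatives to zero. The mapping from continuous expression units to
molecule counts is genuinely underdetermined (array intensities have no
canonical copy-number scale), so we use the minimal convention and flag it
here rather than hide it: panels whose means sit near zero will produce many
zero-copy genes by clipping, which is intended — it is the ground-truth
analogue of a gene being off.

Each cell consumes a random stream derived from (seed, cell index), so
per-cell sampling order — serial or parallel — cannot change the result.

## The sequencing library

The library is built once and sequenced many times, exactly as a physical
library is loaded onto multiple flow cells. It has four parts:

- **Fragment library** — one record per true mRNA copy, storing 0-based
  half-open (start, end) on the forward strand of its transcript. Head and
  tail truncation lengths are drawn independently from a geometric
  distribution (support starting at 0) whose mean is `mean_trunc_frac`
  (default 10%) of the transcript length; a draw with start ≥ end is redrawn
  up to ten times, then emitted full-length. The geometric is our choice —
  memoryless decay is the simplest defensible model for degradation from an
  end, and its single parameter is transparent to override.
- **Barcode bank** — one barcode per cell, drawn by rejection sampling until
  all pairwise Hamming distances reach `min_hamming` (default 2, barcode
  length 16). Distance 2 guarantees one sequencing error can never convert a
  valid barcode into another valid one; distance 3 would additionally make
  Hamming-1 rescue unambiguous. The sampler has a bounded attempt budget and
  reports infeasible requests instead of looping forever.
- **UMI bank** — one UMI (default length 10) per fragment, uniform over all
  sequences, collisions allowed: real chemistry does not deduplicate its own
  tags, and the quantifier must cope. All PCR copies of a fragment share its
  UMI — that is the entire premise of UMI correction.
- **PCR control ledger** — per fragment, the final molecule count and every
  substitution with its molecule, offset, bases and cycle of origin. Each
  cycle, every molecule duplicates with probability `efficiency` (default
  0.9); each newly synthesised base substitutes with probability
  `mutation_rate` (default 1e-5); daughters inherit all parental mutations.
  The simulation is exact, but clean molecules are only counted, never
  materialised, so cost scales with the (few) mutated lineages. Expected
  copy number after c cycles is (1+efficiency)^c, bounded by 2^c, and the
  dispersion grows with c — the amplification bias that UMI correction
  exists to remove.

`write_library()`/`read_library()` round-trip the library losslessly through
plain tab-separated files (one fragment file per cell) plus a flat key-value
manifest recording parameters, seeds, and the reference checksum.

## Sequencing and the noise model

`sequence_library()` draws `depth` molecules with replacement, each fragment
weighted by its copy number — cluster sampling on a flow cell. Read 2 is the
fragment's reference subsequence with its molecule's PCR mutations applied,
clipped to `read2_len` from the 5' end; shorter fragments read through into
repeated adapter sequence `AGATCGGAAGAGC` (or Ns on request), which keeps
downstream behaviour realistic for trimming-aware tools. The single built-in
assembly rule is droplet-style (read 1 = barcode‖UMI); it is a deliberate
single implementation of a pluggable idea.

Sequencing noise is position- and base-resolved: an error profile gives
substitution probabilities per (cycle position, template base, alternative
base), a quality profile gives Gaussian Phred parameters per (position,
called base, was-substituted), rounded and clamped to [2, 41]. Profile files
are sparse TSVs with `*` wildcards; unspecified cells fall back to a
documented uniform default with a warning. `N` bases are never substituted
and always get quality 2.

Reads are generated in fixed 50,000-read chunks whose seeds derive from the
run seed and chunk index alone. The `threads` argument describes scheduling
intent only; because the chunk grid and streams never depend on it, output
is byte-identical at any thread count — reproducibility is a structural
property, not a promise.

## Quantification

`quantify_reads()` mirrors the standard extract → align → count chain at
desk scale. Demultiplexing accepts exact barcode matches and rescues a read
whose barcode has exactly one bank neighbour at Hamming distance 1;
ambiguous rescues (possible when the bank minimum distance is 2) are
discarded — conservative and deterministic. Gene assignment is either the
simulator's truth tag (an oracle mapper, the right tool for validating the
simulator itself) or a toy exact 31-mer voter capped at 10 Mb of reference;
real data should use a real aligner. UMI deduplication implements the
directional rule: a UMI is absorbed by a Hamming-1 neighbour whose count is
at least twice its own minus one, clusters grown from the most abundant UMI
outward. Exact-match-only deduplication is available as `umi_method =
"exact"` for comparison, and `dedup = FALSE` gives raw read counts — the
pair whose contrast demonstrates amplification-bias correction.

## Evaluation and the benchmark harness

Clusters are annotated with the true label most frequent among their cells;
accuracy is the fraction of cells whose cluster annotation matches their own
label, computed independently at the major and sub level. Because sub labels
nest inside major labels, major accuracy always dominates sub accuracy on
the same assignment. Modal ties break toward the globally more frequent
label, then lexicographically. `random_accuracy()` repeats the score over
uniform permutations of the cluster vector (default 100) to estimate the
chance baseline.

`normalize_counts()` provides count (identity), quantile (classic
sorted-mean substitution, so all cells share one value distribution
afterwards), per-gene z-score, library-size scaling to the median cell
total, log10(x+1), within-cell ranks, and TPM (length-normalised within-cell
relative abundance × 10^6). The log pseudocount of 1 and the median
library-size target are package conventions, stated rather than hidden;
z-scores of zero-variance genes are set to 0; a cell with no counts stays
all-zero under TPM with a warning. The TPM denominator runs over genes
within each cell — the only reading under which the quantity is a per-cell
relative abundance.

`run_benchmark()` executes a grid of normalization × reduction × feature
count × clustering × seed. Reductions are none or PCA (independent component
analysis is deliberately out: it adds a heavy dependency for a method whose
benchmark role PCA already covers). Clusterers: k-means, Ward hierarchical,
batch SOM on a grid sized to the target cluster count, a density-peak
clusterer (Gaussian local density; the k best density × separation points
seed clusters; cells follow their nearest denser neighbour), and the
phenograph scheme (kNN graph, default 30 neighbours, plus Louvain community
detection, which chooses its own cluster count). Grid cells that fail — a
singular reduction, say — are recorded with their error message and the run
continues.

## Numerical and design choices worth knowing

- **Integerisation** of normal draws (round, clip at 0) is the one place the
  ground truth departs from its generating normals; parameter-recovery tests
  therefore compare only genes whose means sit well above zero.
- **Directional dedup threshold** is count(parent) ≥ 2·count(child) − 1,
  the de-facto standard form.
- **Saturation experiments** (recovering the truth *exactly*) need two
  conditions picked in advance: depth of roughly M·(ln F + margin), where M
  is the post-PCR molecule count and F the fragment count, so even
  single-copy fragments are observed; and UMIs long enough (14 in our
  fixtures) that the expected number of Hamming ≤ 1 UMI pairs within any
  (cell, gene) is far below one. At the default UMI length of 10 such near
  pairs arise at a rate of order one per desk-scale run and the directional
  merge would fold genuinely distinct molecules together — a real phenomenon
  worth studying, but a confound in an exactness check.
- **Problem sizes** in the test-suite experiments are desk-scale by design:
  e.g. 100–180 cells, 40–500 genes, depths of 5·10^3–5·10^5 read pairs, 5
  replicate seeds for trend medians, 20 replicates for the UMI-correction
  comparison. They are large enough for the Monte-Carlo tolerances used
  (3 SE) and small enough to run routinely.
- **Depth-trend experiment** uses k-means at the true subcategory count for
  the clustering stage, the stabler of the two default clusterers; graph
  clustering chooses its own granularity, which adds variance orthogonal to
  the depth effect being measured.

## What the synthetic generator does and does not emulate

The generator reproduces: hierarchical cell-type structure with marker
genes, within-type normal expression noise, mRNA-copy discreteness,
fragment-length/truncation variation, amplification bias with heritable PCR
errors, barcode/UMI tag errors, position-dependent sequencing error and
quality, and depth-dependent dropout. It does not emulate: gene–gene
correlation within a cell type (genes are independent given the type),
sequence-dependent amplification or capture bias, polyA-priming positional
bias, doublets or ambient RNA, strand flips, indel errors, or batch
effects. Conclusions from passing tests transfer to real data only insofar
as those mechanisms are not the limiting factor.

## Known limitations

- The intensity-to-copy-number convention makes absolute copy numbers
  unit-dependent; only comparisons across conditions within one panel are
  meaningful.
- The toy k-mer aligner is for tiny references; there is no spliced or
  genome-level alignment.
- The knee heuristic in `estimate_whitelist()` (maximum second difference
  on the log-log rank curve) is serviceable for clean cliffs and no match
  for dedicated cell callers on messy data; supply the true bank when you
  have it.
- Clustering accuracy is measured by majority-label annotation only — the
  measure the benchmark is designed around — not by information-theoretic
  indices.
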