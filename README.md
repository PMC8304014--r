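# scrnasim

Ground-truth-anchored simulation of single-cell RNA-seq **raw data** — and
the machinery to score what analysis pipelines recover from it.

## The problem

Clustering is the centrepiece of most scRNA-seq analyses, but on real data
its accuracy cannot be quantified: the true cell types are unknown. Count
simulators sidestep this by drawing a count matrix from a parametric model,
which erases everything that happens between a molecule and a matrix —
barcode errors, UMI collisions, PCR amplification bias, sequencing errors,
and the quantifier's reaction to each. scrnasim instead fixes a **true mRNA
copy-number matrix** `T[g, c]` with known cell labels and replays the data
generation process:

1. **Ground truth.** A *reference panel* models gene `g` in cell
   subcategory `s` as an independent Normal(μ_gs, σ²_gs) (fit from labelled
   expression samples with ≥ 3 samples per subcategory, per-gene overall
   fallback otherwise, or synthesised from a hierarchical log-normal model
   with planted marker genes). Cells are drawn per subcategory and
   integerised.
2. **Sequencing library.** Every true copy becomes a fragment with geometric
   head/tail truncation, recorded as 0-based (start, end) on its transcript.
   Cells get barcodes with pairwise Hamming distance ≥ 2 (settable); every
   fragment gets a uniform-random UMI. PCR duplicates each molecule per
   cycle with probability *e* and mutates newly synthesised bases at a
   per-base rate, so a fragment's copy number has mean (1+e)^cycles, bound
   2^cycles, and a full mutation ledger. The library persists on disk and is
   re-sequenced at will.
3. **Sequencing.** Molecules are drawn with replacement, weighted by copy
   number; read 1 = barcode‖UMI, read 2 = the mutated cDNA, then
   position/base-resolved substitution errors and Gaussian Phred qualities
   from profile files. Output is gzipped paired FASTQ with the truth
   (cell:gene:copy:molecule) carried in header comments.
4. **Quantification.** Barcode demultiplexing with Hamming-1 rescue, gene
   assignment (truth-tag oracle or toy k-mer voter), and directional UMI
   deduplication (a UMI is absorbed by a Hamming-1 neighbour with count
   ≥ 2n−1) produce the recovered count matrix `X[g, c]`.
5. **Evaluation.** Clusters are annotated by their modal true label;
   accuracy = fraction of cells whose cluster annotation matches their own
   label, at major- and sub-category level, plus a permutation chance
   baseline, dropout/low-count diagnostics, knee-curve cell calling, seven
   normalizations (count, quantile, z-score, library-size, log10, rank,
   TPM), and a normalization × PCA × clustering benchmark grid (k-means,
   hierarchical, SOM, density-peak, kNN+Louvain).

Because the truth is known exactly, sharp statements become testable: with
zero noise and saturating depth the recovered matrix **equals** the truth;
UMI deduplication beats raw counts under amplification bias; accuracy rises
and dropout falls with depth.

## A worked example

```r
library(scrnasim)

panel <- synthesize_reference_panel(panel_spec(n_genes = 100, n_major = 3,
  subs_per_major = 2, markers_per_sub = 4, seed = 1))
truth <- sample_ground_truth(panel, cells_per_subcategory = 10, seed = 1)
truth
#> <ground_truth> 100 genes x 60 cells, 6 subcategories (3 major)
#>   total mRNA copies: 32424; sparsity: 12.5% zeros

ref <- synthesize_transcripts(panel_genes(panel), 150, 600, seed = 1)
lib <- build_library(truth, ref, seed = 1)
lib
#> <seq_library> 60 cells, 32424 fragments, 222370 molecules after PCR
#>   barcode 16bp (min Hamming 2), UMI 10bp, PCR 3 cycles @ 0.90

reads <- sequence_library(lib, ref, depth = 30000, read2_len = 60, seed = 1)
q <- quantify_reads(reads, lib, truth = truth)
q
#> <quant_result> 100 genes x 60 cells (umi counts)
#>   reads: 30000 total, 29997 assigned (483 barcode-corrected), 3 lost to barcode, 0 lost to gene
dropout_ratio(q$counts)
#> [1] 0.2413

N  <- normalize_counts(q$counts, "library_size")
cl <- cluster_cells(prcomp(t(N))$x[, 1:30], "kmeans", k = 6, seed = 1)
rep <- annotate_and_score(cl, truth$cells)
rep
#> <accuracy_report> major 1.0000 / sub 1.0000 over 6 clusters
random_accuracy(cl, truth$cells, n_perm = 100, seed = 1)
#> # A tibble: 1 × 2
#>   random_accuracy_major random_accuracy_sub
#>                   <dbl>               <dbl>
#> 1                 0.476               0.329
```

Reading of the numbers: 60 cells at 500 reads/cell leave a quarter of the
matrix zero, yet the six planted subcategories are recovered perfectly
(accuracy 1.0 at both levels), far above the permutation baseline
(0.48/0.33). Three reads lost their barcode to sequencing errors beyond
Hamming-1 rescue; 483 were rescued.

The same chain runs from a YAML config
(`inst/extdata/example_config.yaml`) via `run_pipeline()`, or from the shell
via the thin CLI in `inst/cli/scrnasim` (`pipeline`, `build-lib`,
`sequence`, `quantify`, `evaluate` subcommands). `tidy()`/`glance()`
methods and `autoplot()`/`plot_knee()` cover the result types.

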