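# Toy end-to-end pipeline configuration for run_pipeline()
outdir: scrnasim_run
seed: 1
panel:
  n_genes: 100
  n_major: 3
  subs_per_major: 2
  markers_per_sub: 4
truth:
  cells_per_subcategory: 10
reference:
  min_len: 150
  max_len: 600
library:
  barcode_length: 16
  umi_length: 10
  min_hamming: 2
  cycles: 3
  efficiency: 0.9
  mutation_rate: 1.0e-5
sequencing:
  depth: 30000
  read2_len: 60
  error_rate: 0.001
quantification:
  mode: truth_tag
  dedup: true
evaluation:
  normalization: library_size
  n_features: 30
  clustering: kmeans
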