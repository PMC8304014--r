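#' Run the full simulation pipeline from a config file
#'
#' Chains panel synthesis, ground-truth sampling, library construction,
#' sequencing, quantification and clustering evaluation, writing every
#' intermediate to `outdir` together with a flat key-value run manifest
#' recording all parameters, derived seeds, and output checksums. A library
#' already present in `outdir` is reused (not rebuilt) when
#' `library.reuse: true`, mirroring the one-library/many-runs design.
#'
#' Config schema (YAML or an equivalent nested list); `sequencing.depth` is
#' the only strictly required field:
#' ```yaml
#' outdir: out/            # default "scrnasim_run"
#' seed: 1
#' panel: {n_genes: 500, n_major: 4, subs_per_major: 3}
#' truth: {cells_per_subcategory: 30}
#' reference: {min_len: 200, max_len: 1500}   # or {fasta: path.fa}
#' library: {barcode_length: 16, umi_length: 10, min_hamming: 2,
#'           cycles: 3, efficiency: 0.9, mutation_rate: 1e-5, reuse: true}
#' sequencing: {depth: 100000, read2_len: 90, error_rate: 0.001, threads: 1}
#' quantification: {mode: truth_tag, dedup: true}
#' evaluation: {normalization: library_size, n_features: 30,
#'              clustering: kmeans}
#' ```
#'
#' @param config path to a YAML file, or a nested list with the same
#'   structure.
#' @return list with `truth`, `library`, `reads` (paths), `quant`
#'   (`quant_result`), `report` (`accuracy_report`), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  check_that(is.list(config), "config must be a file path or a list")
  depth <- config$sequencing$depth
  if (is.null(depth))
    stop("config is missing required field 'sequencing.depth'", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% "scrnasim_run"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("scrnasim")),
                   seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # ground truth
  pconf <- config$panel %||% list()
  pconf$seed <- derive_seed(seed, "panel")
  panel <- synthesize_reference_panel(do.call(panel_spec, pconf))
  cps <- config$truth$cells_per_subcategory %||% 30L
  truth <- sample_ground_truth(panel, cps, seed = derive_seed(seed, "truth"))
  write_counts_mtx(truth$counts, file.path(outdir, "truth"), truth$cells)
  manifest$stage_truth <- sprintf("ok cells=%d genes=%d", ncol(truth$counts),
                                  nrow(truth$counts))

  # transcript reference
  rconf <- config$reference %||% list()
  reference <- if (!is.null(rconf$fasta)) read_fasta(rconf$fasta) else
    synthesize_transcripts(panel_genes(panel),
                           min_len = rconf$min_len %||% 200L,
                           max_len = rconf$max_len %||% 1500L,
                           seed = derive_seed(seed, "ref"))
  fasta_path <- file.path(outdir, "reference.fa.gz")
  if (is.null(rconf$fasta)) write_fasta(reference, fasta_path)

  # sequencing library (reused when already on disk)
  lconf <- config$library %||% list()
  lib_dir <- file.path(outdir, "library")
  reuse <- isTRUE(lconf$reuse %||% TRUE)
  if (reuse && file.exists(file.path(lib_dir, "manifest.txt"))) {
    library <- read_library(lib_dir,
                            expected_checksum = reference_checksum(reference))
    manifest$stage_library <- "reused"
  } else {
    library <- build_library(
      truth, reference,
      barcode_length = lconf$barcode_length %||% 16L,
      min_hamming = lconf$min_hamming %||% 2L,
      umi_length = lconf$umi_length %||% 10L,
      mean_trunc_frac = lconf$mean_trunc_frac %||% 0.1,
      pcr = pcr_params(cycles = lconf$cycles %||% 3L,
                       efficiency = lconf$efficiency %||% 0.9,
                       mutation_rate = lconf$mutation_rate %||% 1e-5,
                       seed = derive_seed(seed, "pcr")),
      seed = derive_seed(seed, "library"))
    write_library(library, lib_dir)
    manifest$stage_library <- sprintf("built fragments=%d",
                                      nrow(library$fragments))
  }

  # sequencing
  sconf <- config$sequencing
  err <- if (!is.null(sconf$error_profile))
    load_error_profile(sconf$error_profile) else
      uniform_error_profile(sconf$error_rate %||% 1e-3)
  qual <- if (!is.null(sconf$quality_profile))
    load_quality_profile(sconf$quality_profile) else default_quality_profile()
  reads <- sequence_library(library, reference, depth = depth,
                            read2_len = sconf$read2_len %||% 90L,
                            error_profile = err, quality_profile = qual,
                            threads = sconf$threads %||% 1L,
                            run_id = sconf$run_id %||% "run1",
                            seed = derive_seed(seed, "sequence"))
  fq <- write_fastq_pair(reads, file.path(outdir, "reads"))
  manifest$stage_sequencing <- sprintf("ok depth=%d", nrow(reads))

  # quantification
  qconf <- config$quantification %||% list()
  quant <- quantify_reads(reads, library, truth = truth,
                          reference = reference,
                          mode = qconf$mode %||% "truth_tag",
                          dedup = qconf$dedup %||% TRUE,
                          umi_method = qconf$umi_method %||% "directional")
  write_counts_mtx(quant$counts, file.path(outdir, "counts"), truth$cells)
  write_kv(as.list(quant$stats), file.path(outdir, "quant_stats.txt"))
  manifest$stage_quantification <- sprintf("ok assigned=%d",
                                           quant$stats$reads_assigned)

  # evaluation: default workflow (normalize -> PCA -> cluster -> score)
  econf <- config$evaluation %||% list()
  N <- normalize_counts(quant$counts, econf$normalization %||% "library_size",
                        lengths = transcript_lengths(reference))
  M <- reduce_features(t(N), "pca", econf$n_features %||% 30L,
                       seed = derive_seed(seed, "eval"))
  cl <- cluster_cells(M, econf$clustering %||% "kmeans",
                      k = econf$k %||% length(unique(truth$cells$sub)),
                      seed = derive_seed(seed, "eval"))
  report <- annotate_and_score(cl, truth$cells)
  write_tsv_plain(report$cluster_map, file.path(outdir, "cluster_map.tsv"))
  write_kv(list(accuracy_major = report$accuracy_major,
                accuracy_sub = report$accuracy_sub,
                dropout_ratio = dropout_ratio(quant$counts),
                low_count_ratio = low_count_ratio(quant$counts)),
           file.path(outdir, "accuracy.txt"))
  manifest$stage_evaluation <- sprintf("ok major=%.4f sub=%.4f",
                                       report$accuracy_major,
                                       report$accuracy_sub)

  for (f in c(fq[["R1"]], fq[["R2"]]))
    manifest[[paste0("md5_", basename(f))]] <- unname(tools::md5sum(f))
  write_kv(manifest, file.path(outdir, "run_manifest.txt"))
  list(truth = truth, library = library, reads = fq, quant = quant,
       report = report, manifest = manifest)
}
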