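# Small fixtures built in code, shared across test files.

# A tiny panel/truth/reference triple: `n_major` majors x `subs_per_major`
# subs, low expression so fragment libraries stay small.
tiny_world <- function(n_genes = 30, n_major = 3, subs_per_major = 1,
                       cells_per_sub = 8, baseline_mean = 0.7,
                       min_len = 80, max_len = 250, seed = 1) {
  n_sub <- n_major * subs_per_major
  panel <- synthesize_reference_panel(panel_spec(
    n_genes = n_genes, n_major = n_major, subs_per_major = subs_per_major,
    baseline_mean = baseline_mean,
    markers_per_sub = max(1, min(3, n_genes %/% (2 * n_sub))), seed = seed))
  truth <- sample_ground_truth(panel, cells_per_sub, seed = seed + 1)
  ref <- synthesize_transcripts(panel_genes(panel), min_len, max_len,
                                seed = seed + 2)
  list(panel = panel, truth = truth, ref = ref)
}

# Hand-built ground truth with explicit counts (genes x cells).
manual_truth <- function(counts, majors, subs) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%02d", seq_len(ncol(counts)))
  scrnasim:::new_ground_truth(
    counts, tibble::tibble(cell_id = colnames(counts), major = majors,
                           sub = subs))
}

# Constant-sequence reference so base identities are predictable.
flat_reference <- function(gene_ids, len = 120, base = "ACGT") {
  scrnasim:::new_transcript_ref(
    stats::setNames(rep(strrep(base, ceiling(len / nchar(base))),
                        length(gene_ids)) |> substr(1, len), gene_ids))
}

# A minimal synthetic seq_library with fully controlled copy numbers,
# bypassing pcr_amplify (for sampling-weight tests).
manual_library <- function(fragments, barcodes, umis, copy_numbers,
                           barcode_length, umi_length) {
  pcr <- structure(list(
    copies = tibble::tibble(fragment_id = fragments$fragment_id,
                            copy_number = as.integer(copy_numbers)),
    mutations = tibble::tibble(fragment_id = integer(0),
                               molecule_index = integer(0),
                               offset = integer(0), ref_base = character(0),
                               alt_base = character(0), cycle = integer(0)),
    params = pcr_params(cycles = 10, efficiency = 1, mutation_rate = 0)),
    class = "pcr_control")
  bank <- structure(barcodes, barcode_length = as.integer(barcode_length),
                    min_hamming = 2L,
                    class = c("barcode_bank", class(barcodes)))
  ub <- structure(umis, umi_length = as.integer(umi_length),
                  class = c("umi_bank", class(umis)))
  scrnasim:::new_seq_library(bank, ub, fragments, pcr,
                             list(format_version = "1"))
}
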