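test_that("demultiplexing matches exactly, rescues unique 1-errors, drops the rest", {
  bank <- structure(tibble::tibble(
    cell_id = c("c1", "c2"),
    barcode = c("AAAAAAAA", "TTTTTTTT")),
    barcode_length = 8L, min_hamming = 8L,
    class = c("barcode_bank", class(tibble::tibble())))

  got <- demultiplex(c("AAAAAAAAGGG", "AAAAAAACGGG", "AAAAAACCGGG",
                       "TTTTTTTAGGG", "GGGGGGGGGGG"), bank)
  expect_equal(got$cell_id, c("c1", "c1", NA, "c2", NA))
  expect_equal(got$corrected, c(FALSE, TRUE, FALSE, TRUE, FALSE))

  # ambiguous Hamming-1 neighbours (possible at bank distance 2) are discarded
  tie_bank <- structure(tibble::tibble(
    cell_id = c("c1", "c2"), barcode = c("AAAA", "AACC")),
    barcode_length = 4L, min_hamming = 2L,
    class = c("barcode_bank", class(tibble::tibble())))
  tie <- demultiplex("AAAC", tie_bank)   # distance 1 from both
  expect_true(is.na(tie$cell_id))
})

test_that("gene assignment works as oracle and as toy k-mer voter", {
  w <- tiny_world(n_genes = 6, cells_per_sub = 3, min_len = 100,
                  max_len = 200, seed = 91)
  lib <- build_library(w$truth, w$ref,
                       pcr = pcr_params(cycles = 1, mutation_rate = 0,
                                        seed = 92), seed = 92)
  reads <- sequence_library(lib, w$ref, depth = 300, read2_len = 60,
                            error_profile = uniform_error_profile(0),
                            seed = 93)
  expect_identical(assign_gene(reads, mode = "truth_tag"), reads$gene_id)

  aligned <- assign_gene(reads, w$ref, mode = "align")
  expect_identical(aligned, reads$gene_id)  # zero-error reads, unique 31-mers

  # adapter-only read 2 maps nowhere
  junk <- reads[1, ]
  junk$seq2 <- substr(strrep("AGATCGGAAGAGC", 6), 1, 60)
  expect_true(is.na(assign_gene(junk, w$ref, mode = "align")))

  big <- scrnasim:::new_transcript_ref(setNames(strrep("ACGT", 3e6), "huge"))
  expect_error(assign_gene(reads, big, mode = "align"), "external aligner")
})

test_that("UMI counting collapses duplicates by the directional rule", {
  reads8 <- tibble::tibble(cell_id = "c1", gene_id = "g1",
                           umi = rep("ACGTACGTAC", 8))
  dedup <- count_with_umi(reads8, "g1", "c1", dedup = TRUE)
  expect_equal(dedup["g1", "c1"], 1L)
  raw <- count_with_umi(reads8, "g1", "c1", dedup = FALSE)
  expect_equal(raw["g1", "c1"], 8L)

  # directional merge: 9:1 at Hamming distance 1 collapses to one molecule
  mix <- tibble::tibble(cell_id = "c1", gene_id = "g1",
                        umi = c(rep("AAAA", 9), "AAAT"))
  expect_equal(count_with_umi(mix, "g1", "c1")["g1", "c1"], 1L)
  # but two well-supported distinct UMIs stay separate
  pair <- tibble::tibble(cell_id = "c1", gene_id = "g1",
                         umi = c(rep("AAAA", 5), rep("AAAT", 5)))
  expect_equal(count_with_umi(pair, "g1", "c1")["g1", "c1"], 2L)
  # exact mode never merges neighbours
  expect_equal(count_with_umi(mix, "g1", "c1", umi_method = "exact")["g1", "c1"],
               2L)
})

test_that("raw counts dominate deduplicated counts elementwise", {
  set.seed(17)
  n <- 600
  assigned <- tibble::tibble(
    cell_id = sample(paste0("c", 1:4), n, TRUE),
    gene_id = sample(paste0("g", 1:6), n, TRUE),
    umi = scrnasim:::random_dna(n, 3))
  genes <- paste0("g", 1:6); cells <- paste0("c", 1:4)
  raw <- count_with_umi(assigned, genes, cells, dedup = FALSE)
  ded <- count_with_umi(assigned, genes, cells, dedup = TRUE)
  exact <- count_with_umi(assigned, genes, cells, umi_method = "exact")
  expect_true(all(raw >= ded))
  expect_true(all(exact >= ded))   # mismatch merging only reduces counts
  expect_equal(sum(raw), n)
})

test_that("quantification statistics satisfy the accounting identity", {
  w <- tiny_world(n_genes = 10, cells_per_sub = 4, seed = 95)
  lib <- build_library(w$truth, w$ref, pcr = pcr_params(cycles = 2, seed = 96),
                       seed = 96)
  # high sequencing error so both discard channels are exercised
  reads <- sequence_library(lib, w$ref, depth = 4000, read2_len = 40,
                            error_profile = uniform_error_profile(0.05),
                            seed = 97)
  q <- quantify_reads(reads, lib, truth = w$truth, reference = w$ref,
                      mode = "align")
  s <- q$stats
  expect_equal(s$reads_total,
               s$reads_assigned + s$reads_discarded_barcode +
                 s$reads_discarded_gene)
  expect_gt(s$reads_discarded_barcode, 0)
  expect_gt(s$reads_barcode_corrected, 0)
})

test_that("the whitelist knee keeps high-count barcodes", {
  counts <- c(setNames(rep(1000L, 50) + (1:50), paste0("real", 1:50)),
              setNames(sample(1:4, 300, TRUE), paste0("noise", 1:300)))
  wl <- estimate_whitelist(counts)
  expect_setequal(wl, paste0("real", 1:50))
})

test_that("FASTQ round trip preserves reads and truth tags", {
  w <- tiny_world(n_genes = 6, cells_per_sub = 2, seed = 98)
  lib <- build_library(w$truth, w$ref, pcr = pcr_params(cycles = 1, seed = 99),
                       seed = 99)
  reads <- sequence_library(lib, w$ref, depth = 200, read2_len = 35, seed = 100)
  dir <- withr::local_tempdir()
  write_fastq_pair(reads, file.path(dir, "x"))
  back <- read_fastq_pair(file.path(dir, "x"))
  expect_equal(as.data.frame(back), as.data.frame(reads[, names(back)]),
               ignore_attr = TRUE)

  # quantification straight from the FASTQ matches in-memory quantification
  q_mem <- quantify_reads(reads, lib, truth = w$truth)
  q_fq <- quantify_reads(back, lib, truth = w$truth)
  expect_identical(q_mem$counts, q_fq$counts)

  # empty read set still writes a valid (empty) pair
  write_fastq_pair(reads[0, ], file.path(dir, "empty"))
  empty <- read_fastq_pair(file.path(dir, "empty"))
  expect_equal(nrow(empty), 0)

  bad <- reads
  bad$qual2 <- substr(bad$qual2, 1, 10)
  expect_error(write_fastq_pair(bad, file.path(dir, "bad")), "mismatch")
})
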