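test_that("fragmentation conserves copies and respects coordinates", {
  w <- tiny_world(n_genes = 15, cells_per_sub = 5, seed = 21)
  frags <- fragment_transcripts(w$truth, w$ref, seed = 22)

  # one record per true mRNA copy, for every (cell, gene)
  per_cg <- table(frags$cell_id, frags$gene_id)
  for (cell in colnames(w$truth$counts)) {
    got <- per_cg[cell, rownames(w$truth$counts)[w$truth$counts[, cell] > 0]]
    expect_equal(as.vector(got),
                 as.vector(w$truth$counts[w$truth$counts[, cell] > 0, cell]))
  }
  lens <- transcript_lengths(w$ref)[frags$gene_id]
  expect_true(all(frags$start >= 0 & frags$start < frags$end &
                    frags$end <= lens))

  # no-truncation limit: full-length fragments
  full <- fragment_transcripts(w$truth, w$ref, mean_trunc_frac = 0, seed = 23)
  expect_true(all(full$start == 0))
  expect_equal(as.vector(full$end),
               as.vector(transcript_lengths(w$ref)[full$gene_id]),
               ignore_attr = TRUE)

  # a gene expressed but absent from the reference is an error naming it
  ref2 <- w$ref[names(w$ref) != "g001"]
  ref2 <- scrnasim:::new_transcript_ref(unclass(ref2))
  expect_error(fragment_transcripts(w$truth, ref2, seed = 2), "g001")
})

test_that("truncation lengths follow the configured geometric model", {
  counts <- matrix(2000L, 1, 1, dimnames = list("g1", "cell_01"))
  truth <- manual_truth(counts, "A", "A.1")
  ref <- flat_reference("g1", len = 1000)
  frags <- fragment_transcripts(truth, ref, mean_trunc_frac = 0.1, seed = 31)
  # head truncation ~ Geometric with mean 100 (10% of 1000)
  head_trunc <- frags$start
  expect_lt(abs(mean(head_trunc) - 100), 3 * sd(head_trunc) / sqrt(length(head_trunc)) + 3)
  tail_trunc <- 1000 - frags$end
  expect_lt(abs(mean(tail_trunc) - 100), 3 * sd(tail_trunc) / sqrt(length(tail_trunc)) + 3)
})

test_that("barcode banks satisfy the pairwise Hamming constraint", {
  bank <- get_barcode_bank(60, barcode_length = 12, min_hamming = 2, seed = 7)
  expect_equal(nrow(bank), 60)
  expect_true(all(nchar(bank$barcode) == 12))
  expect_false(anyDuplicated(bank$barcode) > 0)
  expect_gte(min(hamming_distances(bank$barcode)), 2)

  b3 <- get_barcode_bank(40, barcode_length = 12, min_hamming = 3, seed = 8)
  expect_gte(min(hamming_distances(b3$barcode)), 3)

  one <- get_barcode_bank(1, barcode_length = 6, seed = 9)
  expect_equal(nrow(one), 1)

  # only 4 distinct length-1 barcodes exist, so 5 are infeasible
  expect_error(get_barcode_bank(5, barcode_length = 1, min_hamming = 1,
                                seed = 10, max_attempts = 5000),
               "infeasible")
})

test_that("UMI banks are uniform draws with birthday-rate collisions", {
  w <- tiny_world(n_genes = 10, cells_per_sub = 4, seed = 41)
  frags <- fragment_transcripts(w$truth, w$ref, seed = 42)
  bank <- get_umi_bank(frags, umi_length = 10, seed = 43)
  expect_equal(nrow(bank), nrow(frags))
  expect_true(all(nchar(bank$umi) == 10))
  expect_identical(bank, get_umi_bank(frags, umi_length = 10, seed = 43))

  # collision frequency at a tiny UMI space matches the uniform occupancy
  # expectation E[#distinct] = S * (1 - (1 - 1/S)^n), S = 4^3, n = 100
  s <- 64
  n <- 100
  expected_distinct <- s * (1 - (1 - 1 / s)^n)
  keys <- tibble::tibble(fragment_id = seq_len(n))
  observed <- vapply(1:30, function(r)
    length(unique(get_umi_bank(keys, umi_length = 3, seed = 1000 + r)$umi)),
    numeric(1))
  se <- sd(observed) / sqrt(length(observed))
  expect_lt(abs(mean(observed) - expected_distinct), 3 * se)
})

test_that("PCR amplification matches the branching-process model", {
  frags <- tibble::tibble(fragment_id = 1:10000, cell_id = "c1",
                          gene_id = "g1", copy_index = 1:10000,
                          start = 0L, end = 100L)
  ref <- flat_reference("g1", len = 100)

  # certain duplication: exactly 2^3 molecules, no mutations at rate 0
  p8 <- pcr_amplify(frags, ref, pcr_params(cycles = 3, efficiency = 1,
                                           mutation_rate = 0, seed = 1))
  expect_true(all(p8$copies$copy_number == 8))
  expect_equal(nrow(p8$mutations), 0)

  # no cycles: nothing happens
  p0 <- pcr_amplify(frags, ref, pcr_params(cycles = 0, seed = 2))
  expect_true(all(p0$copies$copy_number == 1))
  expect_equal(nrow(p0$mutations), 0)

  # Monte-Carlo mean matches (1+e)^c within 3 SE; bound 2^c always holds
  p <- pcr_amplify(frags, ref, pcr_params(cycles = 3, efficiency = 0.8,
                                          mutation_rate = 0, seed = 3))
  cn <- p$copies$copy_number
  expect_true(all(cn <= 2^3))
  se <- sd(cn) / sqrt(length(cn))
  expect_lt(abs(mean(cn) - 1.8^3), 3 * se)

  # dispersion grows with cycle count (more substrate, more divergence)
  p6 <- pcr_amplify(frags, ref, pcr_params(cycles = 6, efficiency = 0.8,
                                           mutation_rate = 0, seed = 4))
  expect_gt(var(p6$copies$copy_number), var(cn))
})

test_that("PCR mutations carry valid provenance", {
  frags <- tibble::tibble(fragment_id = 1:2000, cell_id = "c1",
                          gene_id = "g1", copy_index = 1:2000,
                          start = 10L, end = 90L)
  ref <- flat_reference("g1", len = 100)
  p <- pcr_amplify(frags, ref, pcr_params(cycles = 3, efficiency = 0.9,
                                          mutation_rate = 2e-3, seed = 5))
  mu <- p$mutations
  expect_gt(nrow(mu), 10)
  expect_true(all(mu$offset >= 0 & mu$offset < 80))
  expect_true(all(mu$alt_base != mu$ref_base))
  expect_true(all(mu$cycle >= 1 & mu$cycle <= 3))
  # molecule indices must exist within their fragment's copy number
  cn <- setNames(p$copies$copy_number, p$copies$fragment_id)
  expect_true(all(mu$molecule_index >= 1 &
                    mu$molecule_index <= cn[as.character(mu$fragment_id)]))
  # provenance chain: replaying each molecule's mutations in cycle order
  # from the reference fragment must find ref_base in place every time
  # (a later mutation at an already-mutated offset records the current base)
  frag_seq <- substr(strrep("ACGT", 25), 11, 90)
  by_mol <- split(mu, paste(mu$fragment_id, mu$molecule_index))
  ok <- vapply(by_mol, function(rows) {
    rows <- rows[order(rows$cycle), ]
    s <- frag_seq
    for (r in seq_len(nrow(rows))) {
      if (substr(s, rows$offset[r] + 1, rows$offset[r] + 1) != rows$ref_base[r])
        return(FALSE)
      substr(s, rows$offset[r] + 1, rows$offset[r] + 1) <- rows$alt_base[r]
    }
    TRUE
  }, logical(1))
  expect_true(all(ok))
})

test_that("library round trip through disk is lossless and reads fail loudly", {
  w <- tiny_world(n_genes = 8, cells_per_sub = 3, seed = 51)
  lib <- build_library(w$truth, w$ref, umi_length = 8,
                       pcr = pcr_params(cycles = 2, seed = 52), seed = 52)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir, expected_checksum = scrnasim:::reference_checksum(w$ref))
  expect_equal(back$barcodes, lib$barcodes)
  expect_equal(back$umis, lib$umis)
  expect_equal(back$fragments, lib$fragments)
  expect_equal(back$pcr$copies, lib$pcr$copies)
  expect_equal(back$pcr$mutations, lib$pcr$mutations)
  expect_equal(back$pcr$params, lib$pcr$params)

  expect_warning(read_library(dir, expected_checksum = "deadbeef"), "checksum")

  file.remove(file.path(dir, "umis.tsv"))
  expect_error(read_library(dir), "umi")
})

test_that("sequencing reuses a stored library without touching it", {
  w <- tiny_world(n_genes = 8, cells_per_sub = 3, seed = 61)
  lib <- build_library(w$truth, w$ref, pcr = pcr_params(cycles = 2, seed = 62),
                       seed = 62)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  before <- tools::md5sum(files)
  stored <- read_library(dir)
  r1 <- sequence_library(stored, w$ref, depth = 500, read2_len = 40, seed = 63)
  r2 <- sequence_library(stored, w$ref, depth = 900, read2_len = 40, seed = 64)
  expect_equal(nrow(r1), 500)
  expect_equal(nrow(r2), 900)
  expect_identical(tools::md5sum(files), before)
})
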