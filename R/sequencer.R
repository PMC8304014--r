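ADAPTER_SEQ <- "AGATCGGAAGAGC"   # read-through padding for short fragments
CHUNK_SIZE <- 50000L             # reads per processing chunk (fixed, so the
                                 # chunk grid never depends on thread count)

#' Apply sequencing substitutions and draw base qualities
#'
#' Each base of each read is independently substituted according to the error
#' profile cell for its cycle position and template base; its Phred quality
#' is then drawn from the quality profile cell matching (position, called
#' base, was-substituted), rounded, and clamped to \[2, 41\]. `N` bases are
#' never substituted and always get quality 2. Positions beyond the profile
#' reuse its last row. Consumes the current RNG stream.
#'
#' @param seqs character vector of equal-length sequences over ACGTN.
#' @param error_profile an `error_profile`.
#' @param quality_profile a `quality_profile`.
#' @return list with `seq` (noisy sequences) and `qual` (Phred+33 strings).
#' @export
apply_sequencing_noise <- function(seqs, error_profile, quality_profile) {
  n <- length(seqs)
  if (n == 0) return(list(seq = character(0), qual = character(0)))
  len <- unique(nchar(seqs))
  check_that(length(len) == 1L, "all sequences must share one length")
  m <- string_to_int_matrix(seqs)
  p <- error_profile$p
  tot <- apply(p, c(1, 2), sum)
  cum <- array(0, dim = dim(p))
  for (a in 1:4) cum[, , a] <- if (a == 1) p[, , 1] else cum[, , a - 1] + p[, , a]
  q <- matrix(QUAL_MIN, n, len)

  for (j in seq_len(len)) {
    pj <- min(j, error_profile$max_len)
    qj <- min(j, quality_profile$max_len)
    b <- m[, j]
    acgt <- b <= 4L
    u <- runif(n)
    perr <- rep(0, n)
    perr[acgt] <- tot[pj, b[acgt]]
    err <- acgt & (u < perr)
    if (any(err)) {
      be <- b[err]
      r <- runif(sum(err)) * tot[pj, be]
      cj <- cbind(cum[pj, be, 1], cum[pj, be, 2], cum[pj, be, 3])
      alt <- 1L + (r > cj[, 1]) + (r > cj[, 2]) + (r > cj[, 3])
      m[err, j] <- alt
    }
    qm <- rep(NA_real_, n); qs <- rep(NA_real_, n)
    ok <- acgt & !err
    bnow <- m[, j]
    qm[ok] <- quality_profile$mean_q[qj, bnow[ok]]
    qs[ok] <- quality_profile$sd_q[qj, bnow[ok]]
    qm[err] <- quality_profile$error_mean_q[qj, bnow[err]]
    qs[err] <- quality_profile$error_sd_q[qj, bnow[err]]
    draw <- round(rnorm(n, ifelse(is.na(qm), QUAL_MIN, qm),
                        ifelse(is.na(qs), 0, qs)))
    qcol <- pmin(pmax(draw, QUAL_MIN), QUAL_MAX)
    qcol[!acgt] <- QUAL_MIN
    q[, j] <- qcol
  }
  qlut <- vapply(0:60, function(i) intToUtf8(33L + i), character(1))
  qual <- do.call(paste0, lapply(seq_len(len), function(j) qlut[q[, j] + 1L]))
  list(seq = int_matrix_to_string(m), qual = qual)
}

#' Sequence a stored library into paired reads at a chosen depth
#'
#' Draws `depth` molecules from the amplified library with replacement,
#' weighting every fragment by its post-PCR copy number (so amplification
#' bias propagates into read counts, as on a real flow cell). For each drawn
#' molecule, read 1 is the cell barcode followed by the fragment's UMI and
#' read 2 is the fragment's reference subsequence with that molecule's PCR
#' mutations applied, clipped to `read2_len` from the 5' end; fragments
#' shorter than `read2_len` read through into repeated adapter sequence
#' (`AGATCGGAAGAGC`), or `N`s with `pad = "N"`. Sequencing substitutions and
#' qualities are then injected per the profiles.
#'
#' Reads are generated in fixed-size chunks whose random streams are derived
#' from `seed` and the chunk index alone; `threads` only describes how chunks
#' may be scheduled, so output is byte-identical for any thread count.
#'
#' @param library a `seq_library` (in memory or from [read_library()]).
#' @param reference the `transcript_ref` the library was built from.
#' @param depth number of read pairs to emit (>= 1).
#' @param read2_len cDNA read length (default 90).
#' @param error_profile,quality_profile profiles; defaults are a flat 1e-3
#'   error rate and the default Gaussian qualities.
#' @param threads advisory worker count (does not affect output).
#' @param pad `"adapter"` (default) or `"N"` padding for short fragments.
#' @param run_id run identifier embedded in read names.
#' @param seed integer seed.
#' @return tibble of class `read_set` with columns `read_id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`, `cell_id`, `gene_id`, `copy_index`,
#'   `molecule_index` (the last four are the truth tag, carried in FASTQ
#'   header comments by [write_fastq_pair()]).
#' @export
sequence_library <- function(library, reference, depth, read2_len = 90L,
                             error_profile = uniform_error_profile(),
                             quality_profile = default_quality_profile(),
                             threads = 1L, pad = c("adapter", "N"),
                             run_id = "run1", seed = 1L) {
  check_that(inherits(library, "seq_library"), "library must be a seq_library")
  depth <- as.integer(depth)
  check_that(depth >= 1, "depth must be >= 1")
  check_that(read2_len >= 1, "read2_len must be >= 1")
  check_that(nrow(library$fragments) > 0,
             "cannot sequence an empty library (no fragments)")
  pad <- match.arg(pad)

  frags <- dplyr::arrange(library$fragments, .data$fragment_id)
  copies <- dplyr::arrange(library$pcr$copies, .data$fragment_id)
  check_that(identical(frags$fragment_id, copies$fragment_id),
             "fragment and PCR ledgers disagree")
  barcode_of <- setNames(library$barcodes$barcode, library$barcodes$cell_id)
  umi_of <- dplyr::arrange(library$umis, .data$fragment_id)$umi
  seqs <- unclass(reference)
  muts <- library$pcr$mutations
  has_mut <- nrow(muts) > 0
  if (has_mut) mut_key <- paste(muts$fragment_id, muts$molecule_index)

  n_chunks <- ceiling(depth / CHUNK_SIZE)
  set.seed(derive_seed(seed, "sequence", n_chunks))
  chunk_seeds <- sample.int(2147483646L, n_chunks)

  out <- vector("list", n_chunks)
  for (ci in seq_len(n_chunks)) {
    first <- (ci - 1L) * CHUNK_SIZE + 1L
    last <- min(ci * CHUNK_SIZE, depth)
    nr <- last - first + 1L
    set.seed(chunk_seeds[ci])

    fi <- sample.int(nrow(frags), nr, replace = TRUE,
                     prob = copies$copy_number)
    mol <- 1L + as.integer(floor(runif(nr) * copies$copy_number[fi]))

    frag_seq <- substr(seqs[frags$gene_id[fi]], frags$start[fi] + 1L,
                       frags$end[fi])
    if (has_mut) {
      key <- paste(frags$fragment_id[fi], mol)
      hit <- which(key %in% mut_key)
      for (i in hit) {
        rows <- muts[mut_key == key[i], , drop = FALSE]
        rows <- rows[order(rows$cycle), , drop = FALSE]
        s <- frag_seq[i]
        for (r in seq_len(nrow(rows)))
          substr(s, rows$offset[r] + 1L, rows$offset[r] + 1L) <- rows$alt_base[r]
        frag_seq[i] <- s
      }
    }
    short <- nchar(frag_seq) < read2_len
    if (any(short)) {
      filler <- if (pad == "adapter")
        strrep(ADAPTER_SEQ, ceiling(read2_len / nchar(ADAPTER_SEQ)))
      else strrep("N", read2_len)
      frag_seq[short] <- paste0(frag_seq[short], filler)
    }
    read2_raw <- substr(frag_seq, 1L, read2_len)
    read1_raw <- paste0(barcode_of[frags$cell_id[fi]], umi_of[fi])

    r1 <- apply_sequencing_noise(read1_raw, error_profile, quality_profile)
    r2 <- apply_sequencing_noise(read2_raw, error_profile, quality_profile)
    out[[ci]] <- tibble(
      read_id = sprintf("SCSIM:%s:%d", run_id, seq.int(first, last)),
      seq1 = r1$seq, qual1 = r1$qual, seq2 = r2$seq, qual2 = r2$qual,
      cell_id = frags$cell_id[fi], gene_id = frags$gene_id[fi],
      copy_index = frags$copy_index[fi], molecule_index = mol
    )
  }
  res <- dplyr::bind_rows(out)
  structure(res, run_id = run_id,
            barcode_length = attr(library$barcodes, "barcode_length"),
            umi_length = attr(library$umis, "umi_length"),
            class = c("read_set", class(res)))
}
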