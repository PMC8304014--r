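#' Fragment ground-truth transcripts into a per-copy fragment library
#'
#' Every true mRNA copy of every gene in every cell becomes exactly one
#' fragment record. A fragment is its gene's reference transcript with a
#' random head and tail portion missing: the two truncation lengths are drawn
#' independently from a geometric distribution (support starting at 0) whose
#' mean is `mean_trunc_frac` of the transcript length. Coordinates are
#' 0-based half-open on the forward strand. Draws yielding an empty fragment
#' (start >= end) are redrawn up to `max_redraws` times, then the full-length
#' transcript is emitted.
#'
#' @param truth a `ground_truth` object.
#' @param reference a `transcript_ref`; every gene with a nonzero count must
#'   be present.
#' @param mean_trunc_frac mean truncated fraction per end (default 0.1; 0
#'   disables truncation).
#' @param max_redraws redraw budget per copy for empty fragments.
#' @param seed integer seed.
#' @return tibble with columns `fragment_id`, `cell_id`, `gene_id`,
#'   `copy_index`, `start`, `end`, one row per true mRNA copy, ordered by
#'   cell then gene.
#' @export
fragment_transcripts <- function(truth, reference, mean_trunc_frac = 0.1,
                                 max_redraws = 10L, seed = 1L) {
  check_that(inherits(truth, "ground_truth"), "truth must be a ground_truth object")
  check_that(inherits(reference, "transcript_ref"), "reference must be a transcript_ref")
  check_that(mean_trunc_frac >= 0 && mean_trunc_frac < 1,
             "mean_trunc_frac must be in [0, 1)")
  counts <- truth$counts
  expressed <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(expressed, names(reference))
  check_that(length(missing) == 0,
             sprintf("gene(s) with nonzero counts missing from reference: %s",
                     paste(head(missing, 5), collapse = ", ")))

  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(tibble(fragment_id = integer(0), cell_id = character(0),
                  gene_id = character(0), copy_index = integer(0),
                  start = integer(0), end = integer(0)))
  k <- counts[idx]
  long <- tibble(
    cell_id = colnames(counts)[idx[, "col"]],
    gene_id = rownames(counts)[idx[, "row"]],
    n = as.integer(k)
  )
  long <- dplyr::arrange(long, .data$cell_id, .data$gene_id)
  frag <- tibble(
    cell_id = rep(long$cell_id, long$n),
    gene_id = rep(long$gene_id, long$n),
    copy_index = sequence(long$n)
  )
  lens <- transcript_lengths(reference)[frag$gene_id]
  n <- nrow(frag)

  set.seed(derive_seed(seed, "fragments"))
  if (mean_trunc_frac == 0) {
    start <- rep(0L, n); end <- as.integer(lens)
  } else {
    # Geometric(p) on {0,1,...} with mean m = (1-p)/p  =>  p = 1/(m+1)
    p <- 1 / (mean_trunc_frac * lens + 1)
    start <- rgeom(n, p)
    end <- lens - rgeom(n, p)
    bad <- which(start >= end)
    tries <- 0L
    while (length(bad) > 0 && tries < max_redraws) {
      start[bad] <- rgeom(length(bad), p[bad])
      end[bad] <- lens[bad] - rgeom(length(bad), p[bad])
      bad <- bad[start[bad] >= end[bad]]
      tries <- tries + 1L
    }
    if (length(bad) > 0) { start[bad] <- 0L; end[bad] <- lens[bad] }
  }
  frag$start <- as.integer(start)
  frag$end <- as.integer(pmin(end, lens))
  frag$fragment_id <- seq_len(n)
  frag[, c("fragment_id", "cell_id", "gene_id", "copy_index", "start", "end")]
}

#' Generate a bank of cell barcodes with a minimum pairwise Hamming distance
#'
#' Barcodes are drawn uniformly at random and accepted only if their Hamming
#' distance to every already-accepted barcode is at least `min_hamming`
#' (rejection sampling). A distance floor of 2 (the default) guarantees a
#' single sequencing error can never turn one valid barcode into another;
#' a floor of 3 additionally makes single-error correction unambiguous.
#'
#' @param n_cells number of barcodes (>= 1).
#' @param barcode_length barcode length in bases (default 16).
#' @param min_hamming minimum pairwise Hamming distance (default 2).
#' @param seed integer seed.
#' @param max_attempts total candidate budget before giving up (default
#'   `1000 * n_cells`); exhaustion signals an infeasible or near-infeasible
#'   request.
#' @param cell_ids optional cell identifiers (length `n_cells`).
#' @return tibble of class `barcode_bank` with columns `cell_id`, `barcode`;
#'   attributes `barcode_length`, `min_hamming`.
#' @examples
#' bank <- get_barcode_bank(20, barcode_length = 8, seed = 1)
#' min(hamming_distances(bank$barcode))
#' @export
get_barcode_bank <- function(n_cells, barcode_length = 16L, min_hamming = 2L,
                             seed = 1L, max_attempts = 1000L * n_cells,
                             cell_ids = NULL) {
  n_cells <- as.integer(n_cells)
  check_that(n_cells >= 1, "n_cells must be >= 1")
  check_that(barcode_length >= 1, "barcode_length must be >= 1")
  check_that(min_hamming >= 0 && min_hamming <= barcode_length,
             "min_hamming must lie in [0, barcode_length]")
  if (is.null(cell_ids)) cell_ids <- pad_ids("cell_", n_cells)
  check_that(length(cell_ids) == n_cells, "cell_ids length must equal n_cells")

  set.seed(derive_seed(seed, "barcodes"))
  accepted <- matrix(0L, nrow = n_cells, ncol = barcode_length)
  n_acc <- 0L
  attempts <- 0L
  while (n_acc < n_cells) {
    if (attempts >= max_attempts)
      stop(sprintf(paste0("barcode rejection sampling exhausted %d attempts at %d/%d ",
                          "barcodes: %d length-%d barcodes with pairwise Hamming >= %d ",
                          "appears infeasible or near-infeasible"),
                   max_attempts, n_acc, n_cells, n_cells, barcode_length,
                   min_hamming), call. = FALSE)
    cand <- sample.int(4L, barcode_length, replace = TRUE)
    attempts <- attempts + 1L
    ok <- TRUE
    if (n_acc > 0L && min_hamming > 0L) {
      d <- rowSums(accepted[seq_len(n_acc), , drop = FALSE] !=
                     matrix(cand, nrow = n_acc, ncol = barcode_length, byrow = TRUE))
      ok <- all(d >= min_hamming)
    }
    if (ok) {
      n_acc <- n_acc + 1L
      accepted[n_acc, ] <- cand
    }
  }
  barcodes <- int_matrix_to_string(accepted)
  out <- tibble(cell_id = cell_ids, barcode = barcodes)
  structure(out, barcode_length = as.integer(barcode_length),
            min_hamming = as.integer(min_hamming),
            class = c("barcode_bank", class(out)))
}

#' All pairwise Hamming distances of a set of equal-length strings
#'
#' @param x character vector of equal-length strings.
#' @return numeric vector of the upper-triangle distances.
#' @export
hamming_distances <- function(x) {
  if (length(x) < 2) return(numeric(0))
  d <- hamming_matrix(x)
  d[upper.tri(d)]
}

#' Generate a UMI bank: one random UMI per fragment
#'
#' UMIs are drawn uniformly and independently over all `4^umi_length`
#' sequences; collisions between fragments are permitted, as they are in real
#' droplet chemistry — the quantifier's deduplication logic has to live with
#' them. All PCR copies of a fragment share its UMI.
#'
#' @param fragments fragment tibble from [fragment_transcripts()] (any tibble
#'   with a `fragment_id` column works).
#' @param umi_length UMI length in bases (default 10).
#' @param seed integer seed.
#' @return tibble with columns `fragment_id`, `umi`.
#' @export
get_umi_bank <- function(fragments, umi_length = 10L, seed = 1L) {
  check_that(umi_length >= 1, "umi_length must be >= 1")
  set.seed(derive_seed(seed, "umis"))
  out <- tibble(fragment_id = fragments$fragment_id,
                umi = random_dna(nrow(fragments), umi_length))
  structure(out, umi_length = as.integer(umi_length),
            class = c("umi_bank", class(out)))
}
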