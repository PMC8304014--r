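#' Synthesize a transcript reference for simulation
#'
#' Generates one random transcript sequence per gene, with lengths drawn
#' uniformly in `[min_len, max_len]`. Useful wherever a real transcriptome
#' FASTA is unnecessary — unit tests, benchmark runs on synthetic panels.
#'
#' @param gene_ids character vector of gene identifiers (unique).
#' @param min_len,max_len transcript length range in bases (default 200-1500,
#'   a desk-scale stand-in for typical mRNA lengths).
#' @param seed integer seed.
#' @return a named character vector of class `transcript_ref` (names = gene
#'   ids, values = sequences over ACGT).
#' @examples
#' ref <- synthesize_transcripts(c("g1", "g2"), 50, 100, seed = 1)
#' nchar(ref)
#' @export
synthesize_transcripts <- function(gene_ids, min_len = 200L, max_len = 1500L,
                                   seed = 1L) {
  check_that(!anyDuplicated(gene_ids), "gene ids must be unique")
  check_that(min_len >= 1 && max_len >= min_len, "invalid length range")
  set.seed(derive_seed(seed, "transcripts"))
  lens <- sample.int(max_len - min_len + 1L, length(gene_ids), replace = TRUE) +
    min_len - 1L
  seqs <- vapply(lens, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                         collapse = ""), character(1))
  new_transcript_ref(setNames(seqs, gene_ids))
}

#' @keywords internal
new_transcript_ref <- function(seqs) {
  check_that(length(seqs) > 0, "transcript reference is empty")
  check_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
             "transcript ids must be present and unique")
  check_that(all(nchar(seqs) >= 1), "transcript lengths must be >= 1")
  bad <- grepl("[^ACGTN]", seqs)
  check_that(!any(bad),
             sprintf("transcript(s) %s contain characters outside ACGTN",
                     paste(head(names(seqs)[bad], 3), collapse = ", ")))
  structure(seqs, class = "transcript_ref")
}

#' Transcript lengths in bases
#' @param reference a `transcript_ref`.
#' @return named integer vector of lengths.
#' @export
transcript_lengths <- function(reference) {
  setNames(nchar(unclass(reference)), names(reference))
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat(sprintf("<transcript_ref> %d transcripts, %d-%d bases\n",
              length(x), min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read a transcript reference from FASTA
#'
#' Gencode-style headers are tolerated: the record id is the first
#' whitespace-delimited token. Sequences are uppercased; characters outside
#' ACGTN are rejected.
#'
#' @param path FASTA file (optionally gzipped).
#' @return a `transcript_ref`.
#' @export
read_fasta <- function(path) {
  check_that(file.exists(path), sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  check_that(length(ss) > 0, sprintf("FASTA file is empty: %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  check_that(!anyDuplicated(ids),
             sprintf("duplicate transcript id(s): %s",
                     paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", ")))
  new_transcript_ref(setNames(toupper(as.character(ss)), ids))
}

#' Write a transcript reference to FASTA
#' @param reference a `transcript_ref`.
#' @param path output file; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(unclass(reference))
  names(ss) <- names(reference)
  Biostrings::writeXStringSet(ss, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
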