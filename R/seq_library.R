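#' Build the complete persistent sequencing library
#'
#' Chains the four library-construction steps — fragmentation, barcode bank,
#' UMI bank, PCR amplification — into the single container that a sequencing
#' run consumes. The library is intentionally decoupled from sequencing:
#' write it once with [write_library()] and re-sequence it at any number of
#' depths and seeds, exactly as a physical library is loaded onto multiple
#' flow cells.
#'
#' @param truth a `ground_truth` object.
#' @param reference a `transcript_ref` covering every expressed gene.
#' @param barcode_length,min_hamming barcode bank parameters (defaults 16, 2).
#' @param umi_length UMI length (default 10).
#' @param mean_trunc_frac fragment truncation parameter, see
#'   [fragment_transcripts()].
#' @param pcr a [pcr_params()] object (its own seed is overridden by a stream
#'   derived from `seed` unless `pcr` is supplied explicitly).
#' @param seed integer master seed; each stage consumes a derived stream.
#' @return object of class `seq_library`: list with `barcodes`
#'   (`barcode_bank`), `umis`, `fragments`, `pcr` (`pcr_control`), and
#'   `manifest` (named list of all parameters and seeds plus a reference
#'   checksum).
#' @examples
#' panel <- synthesize_reference_panel(panel_spec(n_genes = 20, seed = 1))
#' truth <- sample_ground_truth(panel, 3, seed = 1)
#' ref <- synthesize_transcripts(panel_genes(panel), 80, 120, seed = 1)
#' lib <- build_library(truth, ref, seed = 1)
#' @export
build_library <- function(truth, reference, barcode_length = 16L,
                          min_hamming = 2L, umi_length = 10L,
                          mean_trunc_frac = 0.1, pcr = NULL, seed = 1L) {
  if (is.null(pcr)) pcr <- pcr_params(seed = derive_seed(seed, "pcr"))
  fragments <- fragment_transcripts(truth, reference,
                                    mean_trunc_frac = mean_trunc_frac,
                                    seed = derive_seed(seed, "frag"))
  barcodes <- get_barcode_bank(ncol(truth$counts),
                               barcode_length = barcode_length,
                               min_hamming = min_hamming,
                               seed = derive_seed(seed, "bc"),
                               cell_ids = colnames(truth$counts))
  umis <- get_umi_bank(fragments, umi_length = umi_length,
                       seed = derive_seed(seed, "umi"))
  pcr_ctrl <- pcr_amplify(fragments, reference, pcr)
  manifest <- list(
    format_version = "1",
    n_cells = ncol(truth$counts), n_genes = nrow(truth$counts),
    n_fragments = nrow(fragments),
    barcode_length = as.integer(barcode_length),
    min_hamming = as.integer(min_hamming),
    umi_length = as.integer(umi_length),
    mean_trunc_frac = as.numeric(mean_trunc_frac),
    pcr_cycles = pcr$cycles, pcr_efficiency = pcr$efficiency,
    pcr_mutation_rate = pcr$mutation_rate, pcr_seed = pcr$seed,
    seed = as.integer(seed), reference_checksum = reference_checksum(reference)
  )
  new_seq_library(barcodes, umis, fragments, pcr_ctrl, manifest)
}

#' @keywords internal
new_seq_library <- function(barcodes, umis, fragments, pcr, manifest) {
  check_that(identical(sort(umis$fragment_id), sort(fragments$fragment_id)),
             "every fragment must appear exactly once in the UMI bank")
  check_that(identical(sort(pcr$copies$fragment_id), sort(fragments$fragment_id)),
             "every fragment must appear exactly once in the PCR control ledger")
  check_that(all(unique(fragments$cell_id) %in% barcodes$cell_id),
             "every cell with fragments needs a barcode")
  structure(list(barcodes = barcodes, umis = umis, fragments = fragments,
                 pcr = pcr, manifest = manifest),
            class = "seq_library")
}

#' @export
print.seq_library <- function(x, ...) {
  cat(sprintf("<seq_library> %d cells, %d fragments, %.0f molecules after PCR\n",
              nrow(x$barcodes), nrow(x$fragments),
              sum(as.double(x$pcr$copies$copy_number))))
  cat(sprintf("  barcode %dbp (min Hamming %d), UMI %dbp, PCR %d cycles @ %.2f\n",
              attr(x$barcodes, "barcode_length"), attr(x$barcodes, "min_hamming"),
              attr(x$umis, "umi_length"), x$pcr$params$cycles,
              x$pcr$params$efficiency))
  invisible(x)
}

#' @export
glance.seq_library <- function(x, ...) {
  tibble(n_cells = nrow(x$barcodes), n_fragments = nrow(x$fragments),
         total_molecules = sum(as.double(x$pcr$copies$copy_number)),
         n_pcr_mutations = nrow(x$pcr$mutations),
         barcode_length = attr(x$barcodes, "barcode_length"),
         umi_length = attr(x$umis, "umi_length"),
         pcr_cycles = x$pcr$params$cycles)
}

#' Checksum of a transcript reference (md5 over ids and sequences)
#' @keywords internal
reference_checksum <- function(reference) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(names(reference), unclass(reference), sep = "\t"), tf)
  unname(tools::md5sum(tf))
}

write_kv <- function(x, path) {
  writeLines(paste(names(x), vapply(x, as.character, character(1)), sep = "\t"),
             path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(kv, function(p) p[2]), vapply(kv, `[`, character(1), 1))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_plain <- function(path, col_classes = NA) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = col_classes,
                              stringsAsFactors = FALSE))
}

#' Write a sequencing library to disk
#'
#' Directory layout: `manifest.txt` (flat key-value), `barcodes.tsv`,
#' `umis.tsv`, `pcr_copies.tsv`, `pcr_mutations.tsv`, and one fragment file
#' per cell under `fragments/`. All files are plain tab-separated text, so
#' the library is inspectable with shell tools and survives any platform.
#'
#' @param library a `seq_library`.
#' @param path directory to create (must not be an existing non-library
#'   file).
#' @return `path`, invisibly.
#' @seealso [read_library()] for the lossless inverse.
#' @export
write_library <- function(library, path) {
  check_that(inherits(library, "seq_library"), "library must be a seq_library")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "fragments"), showWarnings = FALSE)
  man <- library$manifest
  man$barcode_length <- attr(library$barcodes, "barcode_length")
  man$min_hamming <- attr(library$barcodes, "min_hamming")
  man$umi_length <- attr(library$umis, "umi_length")
  write_kv(man, file.path(path, "manifest.txt"))
  write_tsv_plain(library$barcodes, file.path(path, "barcodes.tsv"))
  write_tsv_plain(library$umis, file.path(path, "umis.tsv"))
  write_tsv_plain(library$pcr$copies, file.path(path, "pcr_copies.tsv"))
  write_tsv_plain(library$pcr$mutations, file.path(path, "pcr_mutations.tsv"))
  write_kv(list(cycles = library$pcr$params$cycles,
                efficiency = library$pcr$params$efficiency,
                mutation_rate = library$pcr$params$mutation_rate,
                seed = library$pcr$params$seed),
           file.path(path, "pcr_params.txt"))
  by_cell <- split(library$fragments, library$fragments$cell_id)
  for (cell in names(by_cell)) {
    write_tsv_plain(by_cell[[cell]],
                    file.path(path, "fragments", paste0(cell, ".tsv")))
  }
  invisible(path)
}

#' Read a sequencing library from disk
#'
#' Lossless inverse of [write_library()]. A missing sub-library file is an
#' error naming the file; a reference checksum mismatch against
#' `expected_checksum` is reported as a warning, not an error, since
#' re-sequencing against a patched reference is sometimes intentional.
#'
#' @param path library directory.
#' @param expected_checksum optional reference checksum to verify against the
#'   manifest.
#' @return a `seq_library`.
#' @export
read_library <- function(path, expected_checksum = NULL) {
  need <- c("manifest.txt", "barcodes.tsv", "umis.tsv", "pcr_copies.tsv",
            "pcr_mutations.tsv", "pcr_params.txt")
  for (f in need) {
    check_that(file.exists(file.path(path, f)),
               sprintf("library at '%s' is missing sub-library file '%s'", path, f))
  }
  check_that(dir.exists(file.path(path, "fragments")),
             sprintf("library at '%s' is missing sub-library file 'fragments/'", path))
  man <- read_kv(file.path(path, "manifest.txt"))
  for (k in c("n_cells", "n_genes", "n_fragments", "barcode_length",
              "min_hamming", "umi_length", "pcr_cycles", "pcr_seed", "seed"))
    if (!is.null(man[[k]])) man[[k]] <- as.integer(man[[k]])
  for (k in c("mean_trunc_frac", "pcr_efficiency", "pcr_mutation_rate"))
    if (!is.null(man[[k]])) man[[k]] <- as.numeric(man[[k]])
  if (!is.null(expected_checksum) &&
      !identical(expected_checksum, man$reference_checksum))
    warning(sprintf("reference checksum mismatch: manifest %s vs supplied %s",
                    man$reference_checksum, expected_checksum))

  barcodes <- read_tsv_plain(file.path(path, "barcodes.tsv"),
                             c("character", "character"))
  barcodes <- structure(barcodes, barcode_length = man$barcode_length,
                        min_hamming = man$min_hamming,
                        class = c("barcode_bank", class(barcodes)))
  umis <- read_tsv_plain(file.path(path, "umis.tsv"),
                         c("integer", "character"))
  umis <- structure(umis, umi_length = man$umi_length,
                    class = c("umi_bank", class(umis)))
  frag_files <- sort(list.files(file.path(path, "fragments"), full.names = TRUE))
  fragments <- dplyr::bind_rows(lapply(frag_files, read_tsv_plain,
    col_classes = c("integer", "character", "character", "integer",
                    "integer", "integer")))
  fragments <- dplyr::arrange(fragments, .data$fragment_id)
  pp <- read_kv(file.path(path, "pcr_params.txt"))
  params <- pcr_params(cycles = as.integer(pp$cycles),
                       efficiency = as.numeric(pp$efficiency),
                       mutation_rate = as.numeric(pp$mutation_rate),
                       seed = as.integer(pp$seed))
  copies <- read_tsv_plain(file.path(path, "pcr_copies.tsv"),
                           c("integer", "integer"))
  mutations <- read_tsv_plain(file.path(path, "pcr_mutations.tsv"),
    c("integer", "integer", "integer", "character", "character", "integer"))
  pcr <- structure(list(copies = copies, mutations = mutations,
                        params = params), class = "pcr_control")
  new_seq_library(barcodes, umis, fragments, pcr, man)
}
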