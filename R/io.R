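#' Write a paired-FASTQ file pair (Phred+33, gzip)
#'
#' Read 1 carries barcode+UMI, read 2 the cDNA. The truth tag
#' (`cell:gene:copy:molecule`) is written as the header comment field, so
#' standard tools ignore it while [read_fastq_pair()] can recover it.
#'
#' @param reads a `read_set` tibble from [sequence_library()] (columns
#'   `read_id`, `seq1`, `qual1`, `seq2`, `qual2`, optional truth-tag
#'   columns).
#' @param prefix output path prefix; files `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` are written.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  check_that(all(nchar(reads$seq1) == nchar(reads$qual1)) &&
               all(nchar(reads$seq2) == nchar(reads$qual2)),
             "sequence/quality length mismatch")
  tag <- if (all(c("cell_id", "gene_id", "copy_index", "molecule_index")
                 %in% names(reads))) {
    paste0(" ", reads$cell_id, ":", reads$gene_id, ":", reads$copy_index,
           ":", reads$molecule_index)
  } else ""
  headers <- paste0(reads$read_id, tag)
  paths <- c(R1 = paste0(prefix, "_R1.fastq.gz"),
             R2 = paste0(prefix, "_R2.fastq.gz"))
  write_one <- function(seqs, quals, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- headers
    Biostrings::writeXStringSet(ss, path, format = "fastq", compress = TRUE,
                                qualities = Biostrings::BStringSet(quals))
  }
  if (nrow(reads) == 0) {
    for (p in paths) {
      con <- gzfile(p, "wb"); close(con)
    }
  } else {
    write_one(reads$seq1, reads$qual1, paths[["R1"]])
    write_one(reads$seq2, reads$qual2, paths[["R2"]])
  }
  invisible(paths)
}

#' Read a paired-FASTQ file pair written by [write_fastq_pair()]
#'
#' @param prefix path prefix used when writing.
#' @return a `read_set` tibble; truth-tag columns are populated when the
#'   header comments carry them.
#' @export
read_fastq_pair <- function(prefix) {
  paths <- c(paste0(prefix, "_R1.fastq.gz"), paste0(prefix, "_R2.fastq.gz"))
  for (p in paths) check_that(file.exists(p), sprintf("FASTQ file not found: %s", p))
  r1 <- Biostrings::readDNAStringSet(paths[1], format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(paths[2], format = "fastq",
                                     with.qualities = TRUE)
  check_that(length(r1) == length(r2), "mate files differ in record count")
  if (length(r1) == 0)
    return(structure(tibble(read_id = character(0), seq1 = character(0),
                            qual1 = character(0), seq2 = character(0),
                            qual2 = character(0)),
                     class = c("read_set", class(tibble()))))
  qual1 <- as.character(S4Vectors::mcols(r1)$qualities)
  qual2 <- as.character(S4Vectors::mcols(r2)$qualities)
  for (q in list(qual1, qual2)) {
    mn <- min(utf8ToInt(paste(q, collapse = "")))
    check_that(mn >= utf8ToInt("!"),
               "quality character below '!' — not Phred+33 encoded")
  }
  headers <- names(r1)
  read_id <- sub("\\s.*$", "", headers)
  comment <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA)
  out <- tibble(read_id = read_id,
                seq1 = as.character(r1), qual1 = qual1,
                seq2 = as.character(r2), qual2 = qual2)
  tags <- strsplit(comment, ":", fixed = TRUE)
  if (all(!is.na(comment)) && all(lengths(tags) == 4L)) {
    out$cell_id <- vapply(tags, `[`, character(1), 1)
    out$gene_id <- vapply(tags, `[`, character(1), 2)
    out$copy_index <- as.integer(vapply(tags, `[`, character(1), 3))
    out$molecule_index <- as.integer(vapply(tags, `[`, character(1), 4))
  }
  structure(out, class = c("read_set", class(out)))
}

#' Write a count matrix as MatrixMarket plus id side tables
#'
#' Files: `matrix.mtx` (sparse integer MTX), `genes.tsv` (one id per line),
#' `cells.tsv` (cell id, plus `major`/`sub` labels when `labels` is given).
#'
#' @param counts integer matrix, genes x cells, with dimnames.
#' @param path output directory (created).
#' @param labels optional tibble (`cell_id`, `major`, `sub`).
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path, labels = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "genes.tsv"))
  if (is.null(labels)) {
    writeLines(colnames(counts), file.path(path, "cells.tsv"))
  } else {
    check_that(identical(labels$cell_id, colnames(counts)),
               "labels must align with matrix columns")
    write_tsv_plain(labels, file.path(path, "cells.tsv"))
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param path directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return list with `counts` (integer matrix) and `labels` (tibble or NULL).
#' @export
read_counts_mtx <- function(path) {
  for (f in c("matrix.mtx", "genes.tsv", "cells.tsv"))
    check_that(file.exists(file.path(path, f)),
               sprintf("count directory '%s' is missing '%s'", path, f))
  m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
  storage.mode(m) <- "integer"
  genes <- readLines(file.path(path, "genes.tsv"))
  first <- readLines(file.path(path, "cells.tsv"), n = 1)
  labels <- NULL
  if (grepl("\t", first)) {
    labels <- read_tsv_plain(file.path(path, "cells.tsv"))
    cells <- labels$cell_id
  } else {
    cells <- readLines(file.path(path, "cells.tsv"))
  }
  dimnames(m) <- list(genes, cells)
  list(counts = m, labels = labels)
}
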