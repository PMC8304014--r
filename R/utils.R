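#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible child seed from a parent seed and a stream label
#'
#' All stochastic stages consume one user-facing seed; internal streams
#' (per-cell sampling, per-chunk read generation) are derived from it with a
#' fixed integer hash so that the order in which streams are consumed — e.g.
#' under parallel scheduling — cannot change the result. Values stay below
#' 2^31 so they are valid R integer seeds.
#'
#' @param seed integer parent seed.
#' @param ... integers and/or strings identifying the stream.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p)) else p <- as.double(p)
    # 64-bit-safe modular mix; constants are arbitrary odd primes
    h <- (h * 48271 + p * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Random DNA strings
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Pairwise Hamming distances between equal-length strings
#'
#' @param x,y character vectors of equal-length strings; with `y` missing the
#'   full symmetric matrix over `x` is returned.
#' @return integer matrix of distances.
#' @keywords internal
hamming_matrix <- function(x, y = NULL) {
  sym <- is.null(y)
  if (sym) y <- x
  lx <- unique(nchar(x)); ly <- unique(nchar(y))
  stopifnot(length(lx) == 1L, length(ly) == 1L, lx == ly)
  mx <- string_to_int_matrix(x)
  my <- string_to_int_matrix(y)
  d <- matrix(0L, nrow = length(x), ncol = length(y))
  for (j in seq_len(lx)) {
    d <- d + outer(mx[, j], my[, j], "!=")
  }
  storage.mode(d) <- "integer"
  d
}

#' Convert equal-length strings to an integer matrix (A=1,C=2,G=3,T=4,N=5)
#' @keywords internal
string_to_int_matrix <- function(x) {
  len <- unique(nchar(x))
  stopifnot(length(len) == 1L)
  codes <- utf8ToInt(paste(x, collapse = ""))
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  matrix(lut[codes], nrow = length(x), ncol = len, byrow = TRUE)
}

#' Inverse of [string_to_int_matrix()]
#' @keywords internal
int_matrix_to_string <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  alphabet <- c(DNA_BASES, "N")
  cols <- lapply(seq_len(ncol(m)), function(j) alphabet[m[, j]])
  do.call(paste0, cols)
}

#' Zero-padded id labels ("cell_007" style)
#' @keywords internal
pad_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(3L, nchar(as.character(n))), seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort unless a condition holds
#' @keywords internal
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
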