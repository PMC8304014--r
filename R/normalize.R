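#' Normalize a count matrix
#'
#' The normalization methods compared by the benchmark harness, all
#' operating on a genes x cells matrix:
#' \describe{
#'   \item{count}{identity — raw counts.}
#'   \item{quantile}{classic quantile normalization across cells (each
#'     column's sorted values are replaced by the mean sorted vector); after
#'     it, every cell has the identical value distribution.}
#'   \item{scale}{per-gene z-score (mean 0, sd 1; genes with zero variance
#'     are set to 0).}
#'   \item{library_size}{per-cell scaling so every cell's total equals the
#'     median cell total.}
#'   \item{log}{`log10(x + 1)`; the pseudocount of 1 makes zeros map to 0.}
#'   \item{rank}{within-cell ranks, average ties.}
#'   \item{tpm}{transcripts-per-million: within each cell,
#'     `(x_g / l_g) / sum_g'(x_g' / l_g') * 1e6` with `l` the transcript
#'     length in bases. Requires `lengths`; a cell with no counts stays all
#'     zero, with a warning.}
#' }
#'
#' @param X numeric matrix, genes x cells.
#' @param method one of the methods above.
#' @param lengths named transcript lengths (bases) covering all genes;
#'   required for `tpm`.
#' @param pre_log apply `log10(x + 1)` before the method (default FALSE);
#'   matches the common practice of log-transforming ahead of scaling or
#'   quantile normalization.
#' @return numeric matrix of the same shape and dimnames.
#' @examples
#' X <- matrix(c(0, 1, 2, 5), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' normalize_counts(X, "log")
#' @export
normalize_counts <- function(X,
                             method = c("count", "quantile", "scale",
                                        "library_size", "log", "rank", "tpm"),
                             lengths = NULL, pre_log = FALSE) {
  method <- match.arg(method)
  check_that(is.matrix(X) && nrow(X) > 0 && ncol(X) > 0,
             "X must be a non-empty matrix")
  if (pre_log) X <- log10(X + 1)
  out <- switch(method,
    count = X,
    quantile = limma::normalizeQuantiles(X, ties = FALSE),
    scale = {
      z <- t(scale(t(X)))
      z[is.nan(z)] <- 0
      z[is.na(z)] <- 0
      z
    },
    library_size = {
      totals <- colSums(X)
      target <- median(totals)
      f <- ifelse(totals > 0, target / totals, 0)
      sweep(X, 2, f, "*")
    },
    log = log10(X + 1),
    rank = apply(X, 2, rank),
    tpm = {
      check_that(!is.null(lengths), "tpm normalization requires transcript lengths")
      l <- lengths[rownames(X)]
      check_that(!anyNA(l) && all(l > 0),
                 "tpm normalization: missing or non-positive transcript length")
      r <- X / l
      tot <- colSums(r)
      if (any(tot == 0))
        warning(sprintf("%d cell(s) with zero counts remain all zero under tpm",
                        sum(tot == 0)))
      f <- ifelse(tot > 0, 1e6 / tot, 0)
      sweep(r, 2, f, "*")
    }
  )
  dimnames(out) <- dimnames(X)
  out
}
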