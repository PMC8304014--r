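#' Score a clustering against the known cell labels by majority annotation
#'
#' Each cluster is annotated with the true label most frequent among its
#' cells (its modal label); accuracy is the fraction of cells whose
#' cluster's annotation equals their own true label. The score is computed
#' independently at the major-category and sub-category level. Modal ties
#' are broken toward the label with larger global frequency, then
#' lexicographically, so annotation is deterministic.
#'
#' @param assignment tibble with columns `cell_id`, `cluster`, or a named
#'   vector/factor of cluster indices.
#' @param labels tibble with columns `cell_id`, `major`, `sub` (e.g.
#'   `truth$cells`).
#' @return object of class `accuracy_report`: list with `accuracy_major`,
#'   `accuracy_sub`, `cluster_map` (tibble `cluster`, `label_major`,
#'   `label_sub`, `size`), and `confusion` (tibble `cluster`, `sub`, `n`).
#' @examples
#' labels <- tibble::tibble(cell_id = c("a", "b", "c"),
#'                          major = c("M1", "M1", "M2"),
#'                          sub = c("M1.1", "M1.1", "M2.1"))
#' cl <- tibble::tibble(cell_id = c("a", "b", "c"), cluster = c(1, 1, 2))
#' annotate_and_score(cl, labels)$accuracy_sub
#' @export
annotate_and_score <- function(assignment, labels) {
  assignment <- as_cluster_tibble(assignment)
  check_that(all(c("cell_id", "major", "sub") %in% names(labels)),
             "labels needs cell_id, major, sub columns")
  check_that(length(intersect(assignment$cell_id, labels$cell_id)) > 0,
             "assignment and labels share no cells")
  check_that(setequal(assignment$cell_id, labels$cell_id),
             "assignment and labels must cover the same cells")
  df <- dplyr::inner_join(assignment, as_tibble(labels), by = "cell_id")

  modal <- function(x, global_freq) {
    tab <- table(x)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) top <- top[order(-global_freq[top], top)][1]
    top
  }
  gmaj <- table(df$major); gsub <- table(df$sub)
  cluster_map <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(label_major = modal(.data$major, gmaj),
                     label_sub = modal(.data$sub, gsub),
                     size = dplyr::n(), .groups = "drop")
  df <- dplyr::left_join(df, cluster_map, by = "cluster")
  confusion <- dplyr::count(df, .data$cluster, .data$sub)
  structure(list(accuracy_major = mean(df$major == df$label_major),
                 accuracy_sub = mean(df$sub == df$label_sub),
                 cluster_map = cluster_map, confusion = confusion),
            class = "accuracy_report")
}

as_cluster_tibble <- function(assignment) {
  if (is_tibble(assignment) || is.data.frame(assignment)) {
    check_that(all(c("cell_id", "cluster") %in% names(assignment)),
               "assignment needs cell_id and cluster columns")
    out <- as_tibble(assignment)[, c("cell_id", "cluster")]
  } else {
    check_that(!is.null(names(assignment)), "cluster vector must be named by cell")
    out <- tibble(cell_id = names(assignment),
                  cluster = as.vector(assignment))
  }
  check_that(!anyNA(out$cluster) && !anyDuplicated(out$cell_id),
             "every cell must carry exactly one cluster index")
  out$cluster <- as.character(out$cluster)
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> major %.4f / sub %.4f over %d clusters\n",
              x$accuracy_major, x$accuracy_sub, nrow(x$cluster_map)))
  invisible(x)
}

#' @export
tidy.accuracy_report <- function(x, ...) x$cluster_map

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble(accuracy_major = x$accuracy_major, accuracy_sub = x$accuracy_sub,
         n_clusters = nrow(x$cluster_map))
}

#' Chance-level accuracy by permuting cluster indices
#'
#' Repeats [annotate_and_score()] after uniformly permuting the cluster
#' index vector across cells, `n_perm` times, and returns the mean — the
#' accuracy a clustering of this shape would get by luck alone.
#'
#' @param assignment,labels as in [annotate_and_score()].
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return tibble with `random_accuracy_major`, `random_accuracy_sub`.
#' @export
random_accuracy <- function(assignment, labels, n_perm = 100L, seed = 1L) {
  check_that(n_perm >= 1, "n_perm must be >= 1")
  assignment <- as_cluster_tibble(assignment)
  set.seed(derive_seed(seed, "perm"))
  acc <- purrr::map(seq_len(n_perm), function(i) {
    perm <- assignment
    perm$cluster <- sample(perm$cluster)
    r <- annotate_and_score(perm, labels)
    c(r$accuracy_major, r$accuracy_sub)
  })
  m <- do.call(rbind, acc)
  tibble(random_accuracy_major = mean(m[, 1]),
         random_accuracy_sub = mean(m[, 2]))
}

#' Dropout ratio: fraction of zero entries in a count matrix
#' @param X numeric matrix (non-empty).
#' @return fraction in \[0, 1\].
#' @export
dropout_ratio <- function(X) {
  check_that(length(X) > 0, "empty matrix")
  mean(X == 0)
}

#' Low-count ratio: fraction of entries in (0, t]
#' @param X numeric matrix (non-empty).
#' @param t threshold (default 1); `Inf` gives `1 - dropout_ratio(X)`.
#' @return fraction in \[0, 1\].
#' @export
low_count_ratio <- function(X, t = 1) {
  check_that(length(X) > 0, "empty matrix")
  check_that(t >= 1, "t must be >= 1")
  mean(X > 0 & X <= t)
}

#' Barcode rank (knee) curve
#'
#' @param counts numeric vector of per-barcode (or per-cell) read counts,
#'   optionally named.
#' @return tibble with `rank`, `barcode`, `count`, sorted by decreasing
#'   count — monotone non-increasing by construction.
#' @export
knee_curve <- function(counts) {
  check_that(length(counts) >= 1, "need at least one barcode")
  if (is.null(names(counts))) names(counts) <- pad_ids("bc", length(counts))
  ord <- order(counts, decreasing = TRUE)
  tibble(rank = seq_along(counts), barcode = names(counts)[ord],
         count = as.numeric(counts[ord]))
}

#' Remove genes claimed by too many clusters from per-cluster marker lists
#'
#' A gene reported as differential for more than four clusters is dropped
#' from every list; genes in at most four clusters are kept. The remaining
#' genes are treated as cluster-specific.
#'
#' @param gene_lists named list (one character vector of genes per cluster).
#' @param max_clusters retention bound (default 4).
#' @return named list of filtered gene vectors.
#' @export
filter_cluster_specific_genes <- function(gene_lists, max_clusters = 4L) {
  if (length(gene_lists) == 0) return(gene_lists)
  occurrence <- table(unlist(lapply(gene_lists, unique)))
  banned <- names(occurrence)[occurrence > max_clusters]
  lapply(gene_lists, function(g) setdiff(g, banned))
}
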