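#' Cluster cells with one of the benchmark's algorithms
#'
#' Standard algorithms invoked as plumbing, all deterministic given `seed`:
#' \describe{
#'   \item{kmeans}{`stats::kmeans`, 10 restarts.}
#'   \item{hierarchical}{Ward linkage on Euclidean distance, cut at `k`.}
#'   \item{som}{batch self-organising map (`class::batchSOM`) on a grid
#'     sized to approximately `k` units; cells are labelled by their
#'     best-matching unit.}
#'   \item{density}{density-peak clustering (Gaussian local density,
#'     distance-to-higher-density separation; the `k` points maximising
#'     density x separation seed the clusters, remaining cells follow their
#'     nearest denser neighbour).}
#'   \item{kmeans_louvain}{k-nearest-neighbour graph (Jaccard-free, plain
#'     kNN with `nn` neighbours) plus Louvain community detection — the
#'     phenograph scheme; the number of clusters is data-driven, `k` is
#'     ignored.}
#' }
#'
#' @param M numeric matrix, cells x features (rownames = cell ids).
#' @param method one of `"kmeans"`, `"hierarchical"`, `"som"`, `"density"`,
#'   `"kmeans_louvain"`.
#' @param k target cluster count (ignored by `kmeans_louvain`).
#' @param nn neighbours for the kNN graph (default 30, capped at n-1).
#' @param seed integer seed.
#' @return tibble with `cell_id`, `cluster`.
#' @export
cluster_cells <- function(M, method = c("kmeans", "hierarchical", "som",
                                        "density", "kmeans_louvain"),
                          k = 2L, nn = 30L, seed = 1L) {
  method <- match.arg(method)
  check_that(is.matrix(M) && nrow(M) >= 2, "M must be a cells x features matrix")
  check_that(!is.null(rownames(M)), "M needs cell ids as rownames")
  set.seed(derive_seed(seed, "cluster", method))
  cl <- switch(method,
    kmeans = kmeans(M, centers = k, nstart = 10, iter.max = 50)$cluster,
    hierarchical = cutree(hclust(dist(M), method = "ward.D2"), k = k),
    som = {
      xd <- max(1L, ceiling(sqrt(k)))
      yd <- max(1L, ceiling(k / xd))
      fit <- class::batchSOM(M, grid = class::somgrid(xd, yd, "rectangular"),
                             radii = c(rep(seq(max(xd, yd), 1), each = 2),
                                       0, 0))
      as.integer(class::knn1(fit$codes, M, seq_len(nrow(fit$codes))))
    },
    density = density_peak_cluster(M, k),
    kmeans_louvain = {
      g <- knn_graph(M, nn = min(nn, nrow(M) - 1L))
      as.integer(igraph::membership(igraph::cluster_louvain(g)))
    }
  )
  tibble(cell_id = rownames(M), cluster = as.character(unname(cl)))
}

#' @keywords internal
knn_graph <- function(M, nn) {
  D <- as.matrix(dist(M))
  n <- nrow(D)
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(nn + 1L)]
    cbind(i, nb)
  })
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::simplify(g)
}

#' Density-peak clustering
#'
#' Local density by a Gaussian kernel at bandwidth `dc` (the
#' `dc_quantile` quantile of pairwise distances); cluster centres are the
#' `k` points with the largest density x separation product; every other
#' point joins the cluster of its nearest neighbour of higher density,
#' assigned in decreasing density order.
#'
#' @param M cells x features matrix.
#' @param k number of clusters.
#' @param dc_quantile bandwidth quantile (default 0.02).
#' @return integer cluster vector.
#' @keywords internal
density_peak_cluster <- function(M, k, dc_quantile = 0.02) {
  D <- as.matrix(dist(M))
  n <- nrow(D)
  off <- D[upper.tri(D)]
  dc <- stats::quantile(off[off > 0], dc_quantile)
  if (!is.finite(dc) || dc <= 0) dc <- mean(off) + 1e-9
  rho <- rowSums(exp(-(D / dc)^2)) - 1
  ord <- order(rho, decreasing = TRUE)
  delta <- numeric(n)
  nneigh <- integer(n)
  delta[ord[1]] <- max(D[ord[1], ])
  nneigh[ord[1]] <- ord[1]
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    nneigh[i] <- j
  }
  centers <- order(rho * delta, decreasing = TRUE)[seq_len(min(k, n))]
  cl <- integer(n)
  cl[centers] <- seq_along(centers)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (cl[i] == 0L) cl[i] <- cl[nneigh[i]]
  }
  cl
}

#' Reduce features before clustering
#' @keywords internal
reduce_features <- function(M, reduction, n_features, seed = 1L) {
  if (reduction == "none") return(M)
  nf <- min(n_features, nrow(M) - 1L, ncol(M))
  set.seed(derive_seed(seed, "reduce"))
  pc <- prcomp(M, center = TRUE, scale. = FALSE, rank. = nf)
  out <- pc$x[, seq_len(nf), drop = FALSE]
  rownames(out) <- rownames(M)
  out
}

#' Run the normalization x reduction x clustering benchmark grid
#'
#' Executes every combination in the grid on one count matrix, scoring each
#' clustering against the true labels with [annotate_and_score()]. Failures
#' of individual grid cells (e.g. a singular reduction) are recorded in the
#' `error` column and the run continues.
#'
#' @param X integer/numeric count matrix, genes x cells.
#' @param labels truth labels tibble (`cell_id`, `major`, `sub`).
#' @param normalizations character vector of [normalize_counts()] methods.
#' @param reductions subset of `c("none", "pca")`.
#' @param n_features feature counts for the reductions (e.g.
#'   `c(100, 70, 40, 10)`; ignored for `"none"`).
#' @param clusterings subset of [cluster_cells()] methods.
#' @param k cluster count handed to the clusterers; defaults to the number
#'   of distinct sub-labels.
#' @param seeds replicate seeds (one grid pass per seed).
#' @param lengths transcript lengths, required when `"tpm"` is among the
#'   normalizations.
#' @param pre_log apply log10(x+1) before each normalization.
#' @return tibble of class `benchmark_result`: one row per grid cell with
#'   `normalization`, `reduction`, `n_features`, `clustering`, `seed`,
#'   `n_clusters`, `accuracy_major`, `accuracy_sub`, `error`.
#' @export
run_benchmark <- function(X, labels,
                          normalizations = c("count", "library_size", "log",
                                             "scale"),
                          reductions = c("pca"),
                          n_features = 30L,
                          clusterings = c("kmeans", "kmeans_louvain"),
                          k = NULL, seeds = 1L, lengths = NULL,
                          pre_log = FALSE) {
  check_that(length(normalizations) > 0 && length(clusterings) > 0 &&
               length(reductions) > 0, "benchmark grid must be non-empty")
  k <- k %||% length(unique(labels$sub))
  grid <- expand_grid(normalization = normalizations,
                      reduction = reductions,
                      n_features = n_features,
                      clustering = clusterings,
                      seed = seeds)
  grid <- grid[!(grid$reduction == "none" &
                   duplicated(paste(grid$normalization, grid$clustering,
                                    grid$seed, grid$reduction))), ]
  norm_cache <- list()
  rows <- purrr::pmap(grid, function(normalization, reduction, n_features,
                                     clustering, seed) {
    res <- tryCatch({
      if (is.null(norm_cache[[normalization]])) {
        norm_cache[[normalization]] <<- normalize_counts(
          X, normalization, lengths = lengths, pre_log = pre_log)
      }
      M <- t(norm_cache[[normalization]])
      M <- reduce_features(M, reduction, n_features, seed = seed)
      cl <- cluster_cells(M, clustering, k = k, seed = seed)
      rep <- annotate_and_score(cl, labels)
      tibble(n_clusters = nrow(rep$cluster_map),
             accuracy_major = rep$accuracy_major,
             accuracy_sub = rep$accuracy_sub, error = NA_character_)
    }, error = function(e) {
      tibble(n_clusters = NA_integer_, accuracy_major = NA_real_,
             accuracy_sub = NA_real_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble(normalization = normalization,
                            reduction = reduction,
                            n_features = n_features,
                            clustering = clustering, seed = seed), res)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("benchmark_result", class(out)))
}

#' Stability summaries of a benchmark table
#'
#' Variance of accuracy across one grid axis, holding the others fixed —
#' e.g. how much a clustering method's accuracy moves when only the
#' normalization changes.
#'
#' @param results a `benchmark_result`.
#' @param over axis to take the variance over (default `"normalization"`).
#' @return tibble with one row per remaining condition and
#'   `var_accuracy_major` / `var_accuracy_sub` columns.
#' @export
summarize_benchmark <- function(results, over = "normalization") {
  fixed <- setdiff(c("normalization", "reduction", "n_features",
                     "clustering", "seed"), over)
  results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(fixed))) |>
    dplyr::summarise(var_accuracy_major = stats::var(.data$accuracy_major),
                     var_accuracy_sub = stats::var(.data$accuracy_sub),
                     n = dplyr::n(), .groups = "drop")
}
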