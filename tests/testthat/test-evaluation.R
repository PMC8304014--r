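labels6 <- tibble::tibble(
  cell_id = paste0("c", 1:6),
  major = c("A", "A", "A", "B", "B", "B"),
  sub = c("A.1", "A.1", "A.1", "B.1", "B.1", "B.1"))

test_that("majority-label scoring follows the stated rule", {
  # perfect clustering: accuracy 1 at both levels
  perfect <- tibble::tibble(cell_id = labels6$cell_id, cluster = labels6$sub)
  r <- annotate_and_score(perfect, labels6)
  expect_equal(r$accuracy_major, 1)
  expect_equal(r$accuracy_sub, 1)

  # one cluster of A x6, B x4: annotated A, accuracy 0.6
  lab10 <- tibble::tibble(cell_id = paste0("c", 1:10),
                          major = rep(c("A", "B"), c(6, 4)),
                          sub = rep(c("A.1", "B.1"), c(6, 4)))
  one <- tibble::tibble(cell_id = lab10$cell_id, cluster = 1)
  r1 <- annotate_and_score(one, lab10)
  expect_equal(r1$accuracy_major, 0.6)
  expect_equal(r1$cluster_map$label_major, "A")

  # clusters {c1: A x3, B x1; c2: B x2} -> c1 = A, c2 = B, accuracy 5/6
  lab <- tibble::tibble(cell_id = paste0("c", 1:6),
                        major = c("A", "A", "A", "B", "B", "B"),
                        sub = c("A.1", "A.1", "A.1", "B.1", "B.1", "B.1"))
  asg <- tibble::tibble(cell_id = paste0("c", 1:6),
                        cluster = c(1, 1, 1, 1, 2, 2))
  r2 <- annotate_and_score(asg, lab)
  expect_equal(r2$accuracy_major, 5 / 6)

  # modal tie breaks toward the globally more frequent label
  lab_tie <- tibble::tibble(cell_id = paste0("c", 1:5),
                            major = c("A", "B", "B", "A", "B"),
                            sub = c("A.1", "B.1", "B.1", "A.1", "B.1"))
  tie <- tibble::tibble(cell_id = paste0("c", 1:5),
                        cluster = c(1, 1, 2, 2, 2))
  rt <- annotate_and_score(tie, lab_tie)
  expect_equal(rt$cluster_map$label_major[rt$cluster_map$cluster == "1"], "B")

  expect_error(
    annotate_and_score(tibble::tibble(cell_id = "zz", cluster = 1), labels6),
    "same cells|no cells")
})

test_that("random accuracy matches exhaustive permutation on a tiny case", {
  asg <- tibble::tibble(cell_id = labels6$cell_id,
                        cluster = c(1, 1, 2, 2, 3, 3))
  # exhaustive oracle: score every one of the 6! arrangements of the
  # cluster-index vector
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  all_acc <- vapply(perms(1:6), function(ord) {
    shuffled <- asg
    shuffled$cluster <- asg$cluster[ord]
    annotate_and_score(shuffled, labels6)$accuracy_major
  }, numeric(1))
  exact <- mean(all_acc)

  mc <- random_accuracy(asg, labels6, n_perm = 3000, seed = 7)
  se <- sd(all_acc) / sqrt(3000)
  expect_lt(abs(mc$random_accuracy_major - exact), 4 * se)

  # a single cluster is permutation-invariant: baseline = modal fraction
  one <- tibble::tibble(cell_id = labels6$cell_id, cluster = 1)
  rb <- random_accuracy(one, labels6, n_perm = 5, seed = 8)
  expect_equal(rb$random_accuracy_major, 0.5)
})

test_that("dropout, low-count and knee metrics follow their definitions", {
  expect_equal(dropout_ratio(matrix(0, 3, 3)), 1)
  expect_equal(dropout_ratio(matrix(c(0, 1, 2, 0), 2)), 0.5)
  expect_equal(dropout_ratio(matrix(1, 2, 2)), 0)

  X <- matrix(c(0, 1, 2, 5), 2)
  expect_equal(low_count_ratio(X, 1), 0.25)
  expect_equal(low_count_ratio(X, Inf), 1 - dropout_ratio(X))
  expect_equal(low_count_ratio(matrix(0, 2, 2), 3), 0)
  expect_error(low_count_ratio(X, 0), ">= 1")

  k <- knee_curve(c(a = 5, b = 1, c = 3))
  expect_equal(k$count, c(5, 3, 1))
  expect_equal(k$barcode, c("a", "c", "b"))
  expect_equal(k$rank, 1:3)
  flat <- knee_curve(rep(4, 5))
  expect_true(all(diff(flat$count) <= 0))
})

test_that("normalizations satisfy their defining identities", {
  set.seed(3)
  X <- matrix(rpois(60, 5), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))

  q <- normalize_counts(X, "quantile")
  sorted <- apply(q, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  s <- normalize_counts(X, "scale")
  expect_true(all(abs(rowMeans(s)) < 1e-12))
  expect_true(all(abs(apply(s, 1, sd) - 1) < 1e-12))

  lens <- setNames(rep(c(100, 200, 300), 2), rownames(X))
  tp <- normalize_counts(X, "tpm", lengths = lens)
  expect_true(all(abs(colSums(tp) - 1e6) < 1e-6))
  # forced length weighting: equal counts, lengths l and 2l -> 2:1 split
  X2 <- matrix(c(4, 4), 2, 1, dimnames = list(c("a", "b"), "c1"))
  tp2 <- normalize_counts(X2, "tpm", lengths = c(a = 100, b = 200))
  expect_equal(as.vector(tp2), c(2 / 3, 1 / 3) * 1e6)
  # a single expressed gene takes the full million
  X3 <- matrix(c(0, 7), 2, 1, dimnames = list(c("a", "b"), "c1"))
  expect_equal(normalize_counts(X3, "tpm", lengths = c(a = 50, b = 50))["b", 1],
               1e6)
  expect_error(normalize_counts(X, "tpm"), "lengths")

  # hand-computed 3 x 3 fixtures for log, rank, library size
  F3 <- matrix(c(0, 9, 99, 3, 3, 3, 1, 0, 0), 3,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  expect_equal(normalize_counts(F3, "log"),
               matrix(c(0, 1, 2, log10(4), log10(4), log10(4), log10(2), 0, 0),
                      3, dimnames = dimnames(F3)))
  expect_equal(normalize_counts(F3, "rank"),
               matrix(c(1, 2, 3, 2, 2, 2, 3, 1.5, 1.5), 3,
                      dimnames = dimnames(F3)))
  # totals are 108, 9, 1; median 9 -> scale factors 9/108, 1, 9
  expect_equal(normalize_counts(F3, "library_size"),
               matrix(c(0, 9 * 9 / 108, 99 * 9 / 108, 3, 3, 3, 9, 0, 0), 3,
                      dimnames = dimnames(F3)))
  expect_equal(normalize_counts(F3, "count"), F3)
})

test_that("over-shared genes are removed from marker lists at the >4 boundary", {
  lists <- list(cl1 = c("a", "b"), cl2 = c("a", "c"), cl3 = c("a", "d"),
                cl4 = c("a", "b"), cl5 = c("a", "e"))
  filtered <- filter_cluster_specific_genes(lists)
  # "a" sits in 5 clusters -> deleted everywhere; "b" in 2 -> kept
  expect_false(any(vapply(filtered, function(g) "a" %in% g, logical(1))))
  expect_true("b" %in% filtered$cl1)

  four <- list(cl1 = "x", cl2 = "x", cl3 = "x", cl4 = "x", cl5 = "y")
  expect_true(all(vapply(filter_cluster_specific_genes(four)[1:4],
                         identical, logical(1), "x")))
  expect_equal(filter_cluster_specific_genes(list()), list())
})

test_that("the benchmark grid runs deterministically and respects label nesting", {
  w <- tiny_world(n_genes = 60, n_major = 2, subs_per_major = 2,
                  cells_per_sub = 12, baseline_mean = 1.2, seed = 111)
  bm <- run_benchmark(w$truth$counts, w$truth$cells,
                      normalizations = c("log", "scale"),
                      reductions = "pca", n_features = 10,
                      clusterings = c("kmeans", "hierarchical"),
                      seeds = c(1, 2))
  expect_true(all(is.na(bm$error)))
  expect_true(all(bm$accuracy_major >= bm$accuracy_sub))
  expect_true(all(bm$accuracy_major >= 0 & bm$accuracy_major <= 1))

  # clearly separated majors are clustered perfectly at k = 2
  bm2 <- run_benchmark(w$truth$counts, w$truth$cells,
                       normalizations = "log", reductions = "pca",
                       n_features = 5, clusterings = "kmeans", k = 2,
                       seeds = 1)
  expect_equal(bm2$accuracy_major, 1)

  expect_identical(
    as.data.frame(run_benchmark(w$truth$counts, w$truth$cells,
                                normalizations = "log", reductions = "pca",
                                n_features = 8, clusterings = "kmeans",
                                seeds = 3)),
    as.data.frame(run_benchmark(w$truth$counts, w$truth$cells,
                                normalizations = "log", reductions = "pca",
                                n_features = 8, clusterings = "kmeans",
                                seeds = 3)))

  sm <- summarize_benchmark(bm, over = "normalization")
  expect_true(all(c("clustering", "var_accuracy_major") %in% names(sm)))
})

test_that("every clustering algorithm separates three obvious blobs", {
  set.seed(5)
  M <- rbind(cbind(rnorm(30, 0), rnorm(30, 0)),
             cbind(rnorm(30, 8), rnorm(30, 8)),
             cbind(rnorm(30, 0), rnorm(30, 16)))
  rownames(M) <- paste0("c", 1:90)
  labels <- tibble::tibble(cell_id = rownames(M),
                           major = rep(c("A", "B", "C"), each = 30),
                           sub = rep(c("A.1", "B.1", "C.1"), each = 30))
  for (m in c("kmeans", "hierarchical", "som", "density", "kmeans_louvain")) {
    cl <- cluster_cells(M, m, k = 3, nn = 10, seed = 4)
    r <- annotate_and_score(cl, labels)
    expect_equal(r$accuracy_major, 1, info = m)
  }
})
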