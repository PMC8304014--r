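#' Reference panel of per-gene, per-subcategory expression distributions
#'
#' A reference panel treats the expression of each gene within each
#' subcategory of cells as an independent normal distribution. It is the
#' statistical description of the cell universe from which ground-truth cells
#' are drawn: one (mean, variance) pair per gene per subcategory, with a
#' per-gene overall fallback used for subcategories too small to fit.
#'
#' The object is a tibble with columns `gene`, `major`, `sub`, `mu`, `var`,
#' `source` (`"subcategory_fit"` or `"overall_fallback"`), one row per
#' (gene, subcategory); the per-gene overall mean/variance sits in the
#' `fallback` attribute.
#'
#' @param tbl tibble with the columns above.
#' @param fallback tibble with columns `gene`, `mu`, `var`.
#' @return an object of class `reference_panel`.
#' @keywords internal
new_reference_panel <- function(tbl, fallback) {
  check_that(nrow(tbl) > 0, "reference panel must contain at least one (gene, subcategory) row")
  check_that(all(c("gene", "major", "sub", "mu", "var", "source") %in% names(tbl)),
             "reference panel is missing required columns")
  check_that(!anyNA(tbl$mu) && !anyNA(tbl$var), "reference panel has undefined (mu, var) entries")
  check_that(all(tbl$var >= 0), "reference panel variances must be non-negative")
  structure(as_tibble(tbl), fallback = as_tibble(fallback),
            class = c("reference_panel", class(as_tibble(tbl))))
}

#' @export
print.reference_panel <- function(x, ...) {
  subs <- dplyr::distinct(as_tibble(x)[, c("major", "sub")])
  cat(sprintf("<reference_panel> %d genes x %d subcategories (%d major categories)\n",
              length(unique(x$gene)), nrow(subs), length(unique(subs$major))))
  NextMethod()
}

#' Subcategories of a reference panel
#'
#' @param panel a `reference_panel`.
#' @return tibble with columns `major`, `sub`, in panel order.
#' @export
panel_subcategories <- function(panel) {
  dplyr::distinct(as_tibble(panel)[, c("major", "sub")])
}

#' Genes of a reference panel
#' @param panel a `reference_panel`.
#' @return character vector of gene identifiers, in panel order.
#' @export
panel_genes <- function(panel) unique(panel$gene)

#' Fit a reference panel from labelled expression samples
#'
#' Each subcategory with at least three samples contributes a per-gene normal
#' fit (sample mean and unbiased, n-1 denominator, sample variance).
#' Subcategories with fewer than three samples fall back to the per-gene
#' overall mean and variance computed across all samples; the `source` column
#' records which route each (gene, subcategory) took. A label that matches no
#' sample at all is an error rather than a silent fallback.
#'
#' @param sample_matrix numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param sample_labels data frame with one row per column of
#'   `sample_matrix`, columns `major` and `sub` (order matches the matrix
#'   columns; an optional `sample` column is checked against colnames).
#' @param min_samples minimum samples for a subcategory-specific fit
#'   (default 3).
#' @return a [new_reference_panel()] object.
#' @examples
#' m <- rbind(g1 = c(2, 4, 6, 1, 1, 8), g2 = c(5, 5, 5, 2, 3, 2))
#' labs <- data.frame(major = c("A", "A", "A", "B", "B", "B"),
#'                    sub = c("A.1", "A.1", "A.1", "B.1", "B.1", "B.1"))
#' fit_reference_panel(m, labs)
#' @export
fit_reference_panel <- function(sample_matrix, sample_labels, min_samples = 3L) {
  sample_matrix <- as.matrix(sample_matrix)
  check_that(nrow(sample_matrix) >= 1 && ncol(sample_matrix) >= 1,
             "sample_matrix must contain at least one gene and one sample")
  check_that(nrow(sample_labels) == ncol(sample_matrix),
             "sample_labels must have one row per sample column")
  check_that(all(c("major", "sub") %in% names(sample_labels)),
             "sample_labels needs 'major' and 'sub' columns")
  if (is.null(rownames(sample_matrix)))
    rownames(sample_matrix) <- pad_ids("g", nrow(sample_matrix))
  genes <- rownames(sample_matrix)

  fallback <- tibble(
    gene = genes,
    mu = unname(rowMeans(sample_matrix)),
    var = unname(apply(sample_matrix, 1, stats::var))
  )
  if (ncol(sample_matrix) < 2) fallback$var <- rep(0, nrow(sample_matrix))

  subs <- dplyr::distinct(as_tibble(sample_labels)[, c("major", "sub")])
  rows <- purrr::pmap(subs, function(major, sub) {
    idx <- which(sample_labels$sub == sub & sample_labels$major == major)
    check_that(length(idx) > 0, sprintf("label (%s, %s) matches no samples", major, sub))
    if (length(idx) >= min_samples) {
      sm <- sample_matrix[, idx, drop = FALSE]
      tibble(gene = genes, major = major, sub = sub,
             mu = unname(rowMeans(sm)), var = unname(apply(sm, 1, stats::var)),
             source = "subcategory_fit")
    } else {
      tibble(gene = genes, major = major, sub = sub,
             mu = fallback$mu, var = fallback$var,
             source = "overall_fallback")
    }
  })
  new_reference_panel(dplyr::bind_rows(rows), fallback)
}

#' Specification for a synthetic reference panel
#'
#' Describes the hierarchical generative model used when no curated
#' expression compendium is at hand: per-gene log-scale baselines, major- and
#' sub-category log-normal perturbations, and a set of marker genes whose
#' mean is raised by `marker_fold` in their own subcategory (relative to the
#' gene's largest mean elsewhere, so markers are discriminative by
#' construction). Per-(gene, subcategory) variance scales with the squared
#' mean via `noise_var_scale`.
#'
#' Defaults give a panel in which the major categories are easily separable
#' and the subcategories only marginally so, the regime where clustering
#' accuracy is sensitive to depth and algorithm choice.
#'
#' @param n_genes number of genes (default 500).
#' @param n_major number of major categories (default 4).
#' @param subs_per_major subcategories per major category (default 3).
#' @param baseline_mean,baseline_sd log-scale gene baseline distribution.
#' @param major_effect_sd,sub_effect_sd log-scale sd of the hierarchical
#'   perturbations.
#' @param markers_per_sub marker genes per subcategory (disjoint across
#'   subcategories; default 5).
#' @param marker_fold fold-change of a marker in its own subcategory
#'   (>= 1, default 4).
#' @param noise_var_scale variance = noise_var_scale * mu^2 (+ a floor of
#'   0.25 so no distribution is degenerate).
#' @param seed integer seed.
#' @return a list of class `panel_spec`.
#' @export
panel_spec <- function(n_genes = 500L, n_major = 4L, subs_per_major = 3L,
                       baseline_mean = 1.0, baseline_sd = 0.6,
                       major_effect_sd = 0.6, sub_effect_sd = 0.25,
                       markers_per_sub = 5L, marker_fold = 4,
                       noise_var_scale = 0.3, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_major = as.integer(n_major),
               subs_per_major = as.integer(subs_per_major),
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               major_effect_sd = major_effect_sd, sub_effect_sd = sub_effect_sd,
               markers_per_sub = as.integer(markers_per_sub),
               marker_fold = marker_fold, noise_var_scale = noise_var_scale,
               seed = as.integer(seed))
  check_that(spec$n_genes >= 1 && spec$n_major >= 1 && spec$subs_per_major >= 1 &&
               spec$markers_per_sub >= 0,
             "panel_spec counts must be positive")
  check_that(spec$baseline_sd >= 0 && spec$major_effect_sd >= 0 &&
               spec$sub_effect_sd >= 0 && spec$noise_var_scale >= 0,
             "panel_spec sd/scale parameters must be non-negative")
  check_that(spec$marker_fold >= 1, "marker_fold must be >= 1")
  structure(spec, class = "panel_spec")
}

#' Synthesize a reference panel from a hierarchical generative model
#'
#' Stand-in for a curated compendium of cell-type expression profiles: draws
#' gene baselines, perturbs them per major category and per subcategory on
#' the log scale, and plants disjoint marker genes per subcategory whose mean
#' is `marker_fold` times the gene's largest mean in any other subcategory.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [panel_spec()].
#' @return a [new_reference_panel()] object; marker assignments are kept in
#'   the `markers` attribute (tibble `gene`, `sub`).
#' @examples
#' panel <- synthesize_reference_panel(panel_spec(n_genes = 60, seed = 7))
#' panel_subcategories(panel)
#' @export
synthesize_reference_panel <- function(spec = panel_spec()) {
  if (!inherits(spec, "panel_spec")) spec <- do.call(panel_spec, spec)
  n_sub <- spec$n_major * spec$subs_per_major
  check_that(spec$markers_per_sub * n_sub <= spec$n_genes,
             sprintf("cannot allocate %d disjoint markers per subcategory across %d subcategories with only %d genes",
                     spec$markers_per_sub, n_sub, spec$n_genes))
  set.seed(derive_seed(spec$seed, "panel"))
  genes <- pad_ids("g", spec$n_genes)
  majors <- pad_ids("M", spec$n_major)
  subs <- tibble(
    major = rep(majors, each = spec$subs_per_major),
    sub = paste0(rep(majors, each = spec$subs_per_major), ".",
                 rep(seq_len(spec$subs_per_major), times = spec$n_major))
  )

  baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  major_eff <- matrix(rnorm(spec$n_genes * spec$n_major, 0, spec$major_effect_sd),
                      nrow = spec$n_genes)
  sub_eff <- matrix(rnorm(spec$n_genes * n_sub, 0, spec$sub_effect_sd),
                    nrow = spec$n_genes)
  major_idx <- rep(seq_len(spec$n_major), each = spec$subs_per_major)
  mu <- exp(baseline + major_eff[, major_idx, drop = FALSE] + sub_eff)

  marker_genes <- sample.int(spec$n_genes, spec$markers_per_sub * n_sub)
  markers <- tibble(
    gene = genes[marker_genes],
    sub = rep(subs$sub, each = spec$markers_per_sub)
  )
  if (spec$markers_per_sub > 0) {
    for (s in seq_len(n_sub)) {
      g <- marker_genes[seq.int((s - 1L) * spec$markers_per_sub + 1L,
                                s * spec$markers_per_sub)]
      others <- apply(mu[g, -s, drop = FALSE], 1, max)
      mu[g, s] <- spec$marker_fold * pmax(mu[g, s], others)
    }
  }

  vr <- spec$noise_var_scale * mu^2 + 0.25
  tbl <- tibble(
    gene = rep(genes, times = n_sub),
    major = rep(subs$major, each = spec$n_genes),
    sub = rep(subs$sub, each = spec$n_genes),
    mu = as.vector(mu), var = as.vector(vr),
    source = "subcategory_fit"
  )
  fb_mu <- rowMeans(mu)
  fb_var <- apply(mu, 1, stats::var) + rowMeans(vr)
  fallback <- tibble(gene = genes, mu = fb_mu, var = fb_var)
  panel <- new_reference_panel(tbl, fallback)
  attr(panel, "markers") <- markers
  attr(panel, "spec") <- spec
  panel
}

#' Sample a ground-truth mRNA copy-number matrix from a reference panel
#'
#' Draws `cells_per_subcategory` cells from every subcategory of the panel;
#' each gene's value is an independent draw from its Normal(mu, var), rounded
#' to the nearest integer with negatives clipped to zero. The rounding and
#' clipping are this package's convention for converting continuous
#' expression units into mRNA copy numbers. Each cell consumes its own
#' derived random stream, so the result does not depend on the order in which
#' cells are generated.
#'
#' @param panel a `reference_panel`.
#' @param cells_per_subcategory cells to draw per subcategory (>= 1).
#' @param seed integer seed.
#' @return an object of class `ground_truth`: a list with `counts` (integer
#'   matrix, genes x cells) and `cells` (tibble `cell_id`, `major`, `sub`).
#' @examples
#' panel <- synthesize_reference_panel(panel_spec(n_genes = 40, seed = 1))
#' truth <- sample_ground_truth(panel, cells_per_subcategory = 5, seed = 2)
#' dim(truth$counts)
#' @export
sample_ground_truth <- function(panel, cells_per_subcategory, seed = 1L) {
  check_that(inherits(panel, "reference_panel"), "panel must be a reference_panel")
  cells_per_subcategory <- as.integer(cells_per_subcategory)
  check_that(cells_per_subcategory >= 1, "cells_per_subcategory must be >= 1")
  subs <- panel_subcategories(panel)
  genes <- panel_genes(panel)
  ptab <- as_tibble(panel)
  mu <- matrix(ptab$mu, nrow = length(genes))   # genes x subs, panel order
  vr <- matrix(ptab$var, nrow = length(genes))
  n_cells <- cells_per_subcategory * nrow(subs)

  counts <- matrix(0L, nrow = length(genes), ncol = n_cells)
  sds <- sqrt(vr)
  for (ci in seq_len(n_cells)) {
    s <- ((ci - 1L) %/% cells_per_subcategory) + 1L
    set.seed(derive_seed(seed, "truth", ci))
    x <- rnorm(length(genes), mu[, s], sds[, s])
    counts[, ci] <- as.integer(pmax(0, round(x)))
  }
  cell_ids <- pad_ids("cell_", n_cells)
  dimnames(counts) <- list(genes, cell_ids)
  cells <- tibble(
    cell_id = cell_ids,
    major = rep(subs$major, each = cells_per_subcategory),
    sub = rep(subs$sub, each = cells_per_subcategory)
  )
  new_ground_truth(counts, cells)
}

#' Construct a ground-truth object
#' @keywords internal
new_ground_truth <- function(counts, cells) {
  check_that(is.matrix(counts) && is.integer(counts), "counts must be an integer matrix")
  check_that(all(counts >= 0), "ground-truth counts must be non-negative")
  check_that(ncol(counts) == nrow(cells), "one label row per cell required")
  check_that(identical(colnames(counts), cells$cell_id), "cell ids must align with matrix columns")
  structure(list(counts = counts, cells = as_tibble(cells)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes x %d cells, %d subcategories (%d major)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sub)), length(unique(x$cells$major))))
  cat(sprintf("  total mRNA copies: %.0f; sparsity: %.1f%% zeros\n",
              sum(as.double(x$counts)), 100 * mean(x$counts == 0)))
  invisible(x)
}

#' @describeIn sample_ground_truth long tibble (cell_id, major, sub, gene,
#'   count) of a `ground_truth` object.
#' @param x a `ground_truth` object.
#' @param ... unused.
#' @export
tidy.ground_truth <- function(x, ...) {
  wide <- as_tibble(x$counts, rownames = "gene")
  long <- pivot_longer(wide, -"gene", names_to = "cell_id", values_to = "count")
  dplyr::left_join(long, x$cells, by = "cell_id")[
    , c("cell_id", "major", "sub", "gene", "count")]
}

#' @export
glance.ground_truth <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_cells = ncol(x$counts),
         n_major = length(unique(x$cells$major)),
         n_sub = length(unique(x$cells$sub)),
         total_copies = sum(as.double(x$counts)),
         dropout = mean(x$counts == 0))
}
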