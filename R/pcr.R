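#' PCR amplification parameters
#'
#' @param cycles number of PCR cycles (>= 0, default 3).
#' @param efficiency per-cycle duplication probability of every molecule
#'   (default 0.9).
#' @param mutation_rate per-base substitution probability during each
#'   duplication (default 1e-5).
#' @param seed integer seed.
#' @return list of class `pcr_params`.
#' @export
pcr_params <- function(cycles = 3L, efficiency = 0.9, mutation_rate = 1e-5,
                       seed = 1L) {
  check_that(cycles >= 0, "cycles must be >= 0")
  check_that(efficiency >= 0 && efficiency <= 1, "efficiency must be in [0,1]")
  check_that(mutation_rate >= 0 && mutation_rate <= 1,
             "mutation_rate must be in [0,1]")
  structure(list(cycles = as.integer(cycles), efficiency = efficiency,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "pcr_params")
}

#' Simulate exponential PCR amplification with a full provenance ledger
#'
#' Each fragment starts as a single molecule. In every cycle, every existing
#' molecule duplicates with probability `efficiency`; each base of a newly
#' synthesised daughter substitutes with probability `mutation_rate`, and a
#' daughter inherits all mutations already present in its parent. The
#' returned control ledger records, per fragment, the final molecule count
#' and every mutation with the molecule it lives on, its offset within the
#' fragment, the reference and substituted base, and the cycle in which it
#' arose — enough to reconstruct any molecule's exact sequence.
#'
#' Mutation-free molecules are never materialised individually (only
#' counted), so the simulation is exact but scales with the number of
#' mutated lineages, which at realistic mutation rates is a small fraction
#' of the library.
#'
#' @param fragments fragment tibble from [fragment_transcripts()].
#' @param reference a `transcript_ref` (provides the reference base at each
#'   mutated offset).
#' @param params a [pcr_params()] object.
#' @return object of class `pcr_control`: list with `copies` (tibble
#'   `fragment_id`, `copy_number`), `mutations` (tibble `fragment_id`,
#'   `molecule_index`, `offset`, `ref_base`, `alt_base`, `cycle`), `params`.
#'   Molecule indices run 1..copy_number per fragment; mutated molecules
#'   occupy the top indices.
#' @examples
#' panel <- synthesize_reference_panel(panel_spec(n_genes = 5, seed = 1))
#' truth <- sample_ground_truth(panel, 2, seed = 1)
#' ref <- synthesize_transcripts(panel_genes(panel), 50, 80, seed = 1)
#' frags <- fragment_transcripts(truth, ref, seed = 1)
#' pcr <- pcr_amplify(frags, ref, pcr_params(cycles = 2, seed = 1))
#' @export
pcr_amplify <- function(fragments, reference, params = pcr_params()) {
  check_that(inherits(params, "pcr_params"), "params must be pcr_params()")
  nf <- nrow(fragments)
  frag_len <- fragments$end - fragments$start
  set.seed(derive_seed(params$seed, "pcr"))

  n <- rep(1L, nf)                       # molecules per fragment
  # mutated molecules, tracked individually; uid is global
  mols <- tibble(uid = integer(0), frag = integer(0))
  muts <- tibble(uid = integer(0), offset = integer(0),
                 ref_base = character(0), alt_base = character(0),
                 cycle = integer(0))
  next_uid <- 1L

  base_at <- function(frag_rows, offsets) {
    # reference base at fragment-relative 0-based offsets
    g <- fragments$gene_id[frag_rows]
    pos <- fragments$start[frag_rows] + offsets + 1L
    unname(substring(unclass(reference)[g], pos, pos))
  }
  draw_alt <- function(cur) {
    vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
           USE.NAMES = FALSE)
  }

  for (cyc in seq_len(params$cycles)) {
    m_count <- tabulate(mols$frag, nbins = nf)
    clean <- n - m_count
    d_clean <- rbinom(nf, clean, params$efficiency)

    # daughters of mutated molecules (inherit parental mutations)
    mut_dup <- if (nrow(mols) > 0) runif(nrow(mols)) < params$efficiency else logical(0)
    daughters <- mols[mut_dup, , drop = FALSE]
    n_daughters <- nrow(daughters)
    if (n_daughters > 0) {
      new_uids <- next_uid + seq_len(n_daughters) - 1L
      next_uid <- next_uid + n_daughters
      inherit <- dplyr::inner_join(muts,
        tibble(uid = daughters$uid, new_uid = new_uids), by = "uid")
      inherit$uid <- inherit$new_uid
      inherit$new_uid <- NULL
      muts <- dplyr::bind_rows(muts, inherit)
      new_mols <- tibble(uid = new_uids, frag = daughters$frag)
      # fresh substitutions while copying a mutated template
      if (params$mutation_rate > 0) {
        k <- rbinom(n_daughters, frag_len[daughters$frag], params$mutation_rate)
        for (i in which(k > 0)) {
          off <- as.integer(floor(runif(k[i]) * frag_len[daughters$frag[i]]))
          cur <- base_at(rep(daughters$frag[i], k[i]), off)
          prior <- muts[muts$uid == new_uids[i] & muts$offset %in% off, ]
          for (r in seq_len(nrow(prior)))
            cur[off == prior$offset[r]] <- prior$alt_base[r]
          muts <- dplyr::bind_rows(muts, tibble(
            uid = new_uids[i], offset = off, ref_base = cur,
            alt_base = draw_alt(cur), cycle = cyc))
        }
      }
      mols <- dplyr::bind_rows(mols, new_mols)
    }

    # fresh substitutions while copying clean templates: each such event
    # turns one clean daughter into a new mutated lineage
    if (params$mutation_rate > 0) {
      k <- rbinom(nf, d_clean * frag_len, params$mutation_rate)
      hit <- which(k > 0)
      for (f in hit) {
        slot <- sample.int(d_clean[f], k[f], replace = TRUE)
        for (s in unique(slot)) {
          off <- as.integer(floor(runif(sum(slot == s)) * frag_len[f]))
          off <- unique(off)
          refb <- base_at(rep(f, length(off)), off)
          mols <- dplyr::bind_rows(mols, tibble(uid = next_uid, frag = f))
          muts <- dplyr::bind_rows(muts, tibble(
            uid = next_uid, offset = off, ref_base = refb,
            alt_base = draw_alt(refb), cycle = cyc))
          next_uid <- next_uid + 1L
        }
      }
    }
    n <- n + d_clean + tabulate(daughters$frag, nbins = nf)
  }

  # final molecule indices: clean molecules take 1..(n-m), mutated the rest
  m_count <- tabulate(mols$frag, nbins = nf)
  if (nrow(mols) > 0) {
    mols <- mols[order(mols$frag, mols$uid), ]
    within <- stats::ave(mols$uid, mols$frag, FUN = seq_along)
    mols$molecule_index <- n[mols$frag] - m_count[mols$frag] + within
    mutations <- dplyr::inner_join(muts, mols, by = "uid")
    mutations <- tibble(fragment_id = fragments$fragment_id[mutations$frag],
                        molecule_index = mutations$molecule_index,
                        offset = mutations$offset,
                        ref_base = mutations$ref_base,
                        alt_base = mutations$alt_base,
                        cycle = mutations$cycle)
    mutations <- dplyr::arrange(mutations, .data$fragment_id,
                                .data$molecule_index, .data$cycle, .data$offset)
  } else {
    mutations <- tibble(fragment_id = integer(0), molecule_index = integer(0),
                        offset = integer(0), ref_base = character(0),
                        alt_base = character(0), cycle = integer(0))
  }
  structure(list(copies = tibble(fragment_id = fragments$fragment_id,
                                 copy_number = n),
                 mutations = mutations, params = params),
            class = "pcr_control")
}

#' @export
print.pcr_control <- function(x, ...) {
  cat(sprintf("<pcr_control> %d fragments -> %.0f molecules (%d cycles, efficiency %.2f)\n",
              nrow(x$copies), sum(as.double(x$copies$copy_number)),
              x$params$cycles, x$params$efficiency))
  cat(sprintf("  mutation events: %d on %d molecules\n", nrow(x$mutations),
              nrow(dplyr::distinct(x$mutations[, c("fragment_id", "molecule_index")]))))
  invisible(x)
}
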