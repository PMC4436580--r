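# Seeded generators for family-like proteins and curation decoys.
#
# Sequences are built from explicit block instantiations separated by random
# filler, then rejection-sampled so that the realized block occurrences are
# exactly the planted ones: the truth labels attached to each record are
# exact, not probabilistic.

sample_residues <- function(n) {
  sample(AA_ALPHABET, n, replace = TRUE)
}

# draw one element; safe for length-1 vectors (no 1:x expansion)
draw1 <- function(x) x[sample.int(length(x), 1)]

instantiate_block <- function(pattern) {
  paste(vapply(pattern$tokens, function(tok) {
    if (length(tok) == 1) tok else sample(tok, 1)
  }, character(1)), collapse = "")
}

# Assemble blocks (in the given order) with filler, then check that every
# pattern occurs exactly at its planted location(s); resample otherwise.
assemble_with_blocks <- function(block_order, patterns, spacing, max_tries = 500) {
  stopifnot(spacing[1] >= 0, spacing[2] >= spacing[1])
  for (try in seq_len(max_tries)) {
    pieces <- character(0)
    starts <- integer(length(block_order))
    pos <- 0L
    for (k in seq_along(block_order)) {
      gap_len <- draw1(seq(spacing[1], spacing[2]))
      filler <- paste(sample_residues(gap_len), collapse = "")
      word <- instantiate_block(patterns[[block_order[k]]])
      pieces <- c(pieces, filler, word)
      starts[k] <- pos + gap_len
      pos <- starts[k] + patterns[[block_order[k]]]$length
    }
    tail_len <- draw1(seq(spacing[1], spacing[2]))
    pieces <- c(pieces, paste(sample_residues(tail_len), collapse = ""))
    seq <- paste(pieces, collapse = "")

    planted <- tibble(
      block = names(patterns)[block_order],
      start = starts,
      end = starts + vapply(patterns[block_order], `[[`, 1L, "length")
    )
    realized <- dplyr::bind_rows(
      purrr::map(patterns, find_block_occurrences, seq = seq)
    )
    key <- function(x) sort(paste(x$block, x$start))
    clean <- nrow(realized) == nrow(planted) &&
      identical(key(realized), key(planted))
    if (clean) {
      return(list(seq = seq, planted = dplyr::arrange(planted, .data$start)))
    }
  }
  stop("failed to assemble a clean synthetic protein in ", max_tries, " tries")
}

#' Generate a synthetic family-true protein
#'
#' Builds a protein carrying one instantiation of each of the five conserved
#' metal-binding blocks, in canonical order and non-overlapping, separated
#' (and flanked) by random filler whose length is drawn uniformly from
#' `spacing`. Filler is rejection-sampled so that the only block occurrences
#' in the sequence are the planted ones; [validate_blocks()] on the result is
#' therefore `valid` by construction.
#'
#' @param seed Integer seed; output is deterministic given the seed.
#' @param spacing Length-2 vector, min and max filler length in residues.
#' @param patterns Compiled block patterns (canonical order).
#' @return One-row tibble: `record_id`, `seq`, `category = "true_pap"` and a
#'   list-column `planted_blocks` of the planted occurrences.
#' @export
#' @examples
#' generate_pap_protein(1)$seq
generate_pap_protein <- function(seed, spacing = c(5, 40),
                                 patterns = compile_block_patterns()) {
  with_seed(seed, {
    res <- assemble_with_blocks(seq_along(patterns), patterns, spacing)
    tibble(
      record_id = sprintf("SYNPAP_%06d", as.integer(seed)),
      seq = res$seq,
      category = "true_pap",
      planted_blocks = list(res$planted)
    )
  })
}

#' Generate a decoy protein for the curation filter
#'
#' Three decoy classes mirror the ways real candidates fail curation:
#' `missing_block` decoys carry exactly four of the five blocks (one dropped
#' at random), `scrambled_order` decoys carry all five blocks but with two
#' adjacent blocks swapped so no canonical-order selection exists, and
#' `random` decoys are i.i.d. residues.
#'
#' @param seed Integer seed.
#' @param mode `"missing_block"`, `"scrambled_order"` or `"random"`.
#' @param spacing Filler length range (ignored for `random`).
#' @param length Sequence length for `random` decoys.
#' @param patterns Compiled block patterns (canonical order).
#' @return One-row tibble like [generate_pap_protein()], with `category` set
#'   to the decoy mode.
#' @export
generate_decoy_protein <- function(seed,
                                   mode = c("missing_block",
                                            "scrambled_order", "random"),
                                   spacing = c(5, 40), length = 200,
                                   patterns = compile_block_patterns()) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "missing_block") {
      drop <- sample(seq_along(patterns), 1)
      res <- assemble_with_blocks(setdiff(seq_along(patterns), drop),
                                  patterns, spacing)
    } else if (mode == "scrambled_order") {
      k <- sample(seq_len(length(patterns) - 1), 1)
      ord <- seq_along(patterns)
      ord[c(k, k + 1)] <- ord[c(k + 1, k)]
      res <- assemble_with_blocks(ord, patterns, spacing)
    } else {
      res <- list(
        seq = paste(sample_residues(length), collapse = ""),
        planted = tibble(block = character(), start = integer(),
                         end = integer())
      )
    }
    tibble(
      record_id = sprintf("SYNDEC_%06d", as.integer(seed)),
      seq = res$seq,
      category = mode,
      planted_blocks = list(res$planted)
    )
  })
}

#' Generate a curation-sized candidate set with known truth
#'
#' Builds a candidate set mixing block-valid proteins with the two decoy
#' classes removed during curation. The default sizes mirror the curation
#' arithmetic of the maize family mining: 33 valid genes, 11 missing-block
#' candidates and 2 scrambled-order candidates (46 in, 33 kept, 13 removed).
#'
#' @param n_true,n_missing,n_scrambled Number of records per category.
#' @param seed Master seed; per-record seeds are split deterministically.
#' @param spacing Filler length range.
#' @return Tibble with columns `gene_id`, `transcript_id`, `is_primary`,
#'   `seq`, `category`, `planted_blocks` (one transcript per gene).
#' @export
#' @examples
#' nrow(generate_candidate_set(seed = 1))
generate_candidate_set <- function(n_true = 33, n_missing = 11,
                                   n_scrambled = 2, seed = 1,
                                   spacing = c(5, 40)) {
  specs <- c(rep("true", n_true), rep("missing_block", n_missing),
             rep("scrambled_order", n_scrambled))
  recs <- purrr::imap(specs, function(cat, i) {
    s <- split_seed(seed, i)
    if (cat == "true") generate_pap_protein(s, spacing = spacing)
    else generate_decoy_protein(s, mode = cat, spacing = spacing)
  }) |> dplyr::bind_rows()
  recs |>
    dplyr::mutate(
      gene_id = sprintf("SYNGENE%04d", dplyr::row_number()),
      transcript_id = paste0(.data$gene_id, "_T01"),
      is_primary = TRUE
    ) |>
    dplyr::select("gene_id", "transcript_id", "is_primary", "seq",
                  "category", "planted_blocks")
}

# Point mutations at a given per-site rate; substitutes with one of the 19
# other residues.
mutate_protein <- function(seq, rate) {
  cs <- chars(seq)
  hit <- runif(length(cs)) < rate
  cs[hit] <- vapply(cs[hit], function(a) sample(setdiff(AA_ALPHABET, a), 1),
                    character(1))
  paste(cs, collapse = "")
}

#' Generate a two-tier divergent protein family
#'
#' Produces a seed family plus a target "proteome" in which core members are
#' moderately diverged from the seed and outlier members are diverged
#' further along the same lineage, so that a profile built from the seed
#' family alone retrieves the core tier while the outliers are only reached
#' once the profile is enriched with first-round hits. Used to exercise
#' iterative (multi-round) profile search.
#'
#' @param seed Master seed.
#' @param n_seed,n_core,n_outlier Family sizes per tier.
#' @param core_divergence Per-site divergence of the core-tier centroid from
#'   the seed-family centroid.
#' @param outlier_divergence Additional per-site divergence of the outlier
#'   centroid from the core centroid.
#' @param within Per-site divergence of members from their tier centroid.
#' @param length Ungapped sequence length (all tiers share it, so the seed
#'   family is trivially aligned).
#' @return List with `seed_msa` (tibble `id`, `seq`) and `targets` (tibble
#'   `record_id`, `seq`, `tier` in `core`/`outlier`).
#' @export
generate_divergent_family <- function(seed, n_seed = 6, n_core = 8,
                                      n_outlier = 3, core_divergence = 0.45,
                                      outlier_divergence = 0.45,
                                      within = 0.05, length = 200) {
  with_seed(seed, {
    ancestor <- paste(sample_residues(length), collapse = "")
    seed_msa <- tibble(
      id = sprintf("SEED%02d", seq_len(n_seed)),
      seq = vapply(seq_len(n_seed), function(i) mutate_protein(ancestor, within),
                   character(1))
    )
    core_centroid <- mutate_protein(ancestor, core_divergence)
    out_centroid <- mutate_protein(core_centroid, outlier_divergence)
    targets <- dplyr::bind_rows(
      tibble(
        record_id = sprintf("CORE%02d", seq_len(n_core)),
        seq = vapply(seq_len(n_core),
                     function(i) mutate_protein(core_centroid, within),
                     character(1)),
        tier = "core"
      ),
      tibble(
        record_id = sprintf("OUTL%02d", seq_len(n_outlier)),
        seq = vapply(seq_len(n_outlier),
                     function(i) mutate_protein(out_centroid, within),
                     character(1)),
        tier = "outlier"
      )
    )
    list(seed_msa = seed_msa, targets = targets)
  })
}
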