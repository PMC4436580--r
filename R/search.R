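# Profile search of a proteome, single-round and iterative (two-round).

as_proteome <- function(proteome) {
  if (is.character(proteome)) {
    proteome <- tibble(target_id = names(proteome) %||%
                         sprintf("T%05d", seq_along(proteome)),
                       seq = unname(proteome))
  }
  id_col <- intersect(c("target_id", "record_id", "id", "gene_id"),
                      names(proteome))[1]
  tibble(target_id = proteome[[id_col]], seq = proteome$seq)
}

#' Search a proteome with a calibrated profile
#'
#' Scores every target sequence against the profile and reports hits with
#' E-value below the inclusion threshold, sorted by ascending E-value (ties
#' broken lexicographically by target id).
#'
#' @param profile A calibrated `pap_profile` (see [calibrate_evalue()]).
#' @param proteome Tibble with id and `seq` columns, or a named character
#'   vector.
#' @param evalue_max Inclusion threshold (default 0.01).
#' @return Tibble: `target_id`, `score`, `evalue`, `span_start`,
#'   `span_end` (0-based half-open).
#' @export
profile_search <- function(profile, proteome, evalue_max = 0.01) {
  proteome <- as_proteome(proteome)
  if (nrow(proteome) == 0) {
    return(tibble(target_id = character(), score = numeric(),
                  evalue = numeric(), span_start = integer(),
                  span_end = integer()))
  }
  hits <- purrr::map2(proteome$target_id, proteome$seq, function(id, s) {
    sc <- score_sequence(profile, s)
    tibble(target_id = id, score = sc$score,
           evalue = evalue(profile, sc$score),
           span_start = sc$span[1], span_end = sc$span[2])
  }) |> dplyr::bind_rows()
  hits |>
    dplyr::filter(.data$evalue < evalue_max) |>
    dplyr::arrange(.data$evalue, .data$target_id)
}

# Stack round-1 hit regions onto the seed alignment's match columns using
# each hit's DP trace (no realignment): per profile column, the aligned
# target residue or a gap.
stack_hits <- function(profile, proteome, hit_ids) {
  rows <- purrr::map(hit_ids, function(id) {
    s <- proteome$seq[match(id, proteome$target_id)]
    sc <- score_sequence(profile, s)
    cs <- chars(toupper(s))
    vapply(sc$col_pos, function(p) if (p > 0) cs[p] else "-", character(1))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- hit_ids
  rbind(profile$seed_match, m)
}

#' Iterative (multi-round) profile search
#'
#' Round 1 searches with a profile built from the seed alignment. Each
#' later round rebuilds the profile from the union of the seed sequences
#' and the previous round's hit regions (stacked by their DP trace against
#' the profile columns), recalibrates, and searches again. The result is
#' the union of hits across rounds, labeled with the first round of
#' discovery, so the candidate set grows monotonically with rounds.
#'
#' @param seed_msa Seed alignment tibble (see [read_msa()]).
#' @param proteome Target sequences (tibble or named character vector).
#' @param rounds Number of rounds (>= 1); 2 reproduces the classic
#'   two-round mining strategy.
#' @param evalue_max Inclusion threshold per round.
#' @param pseudocount,gap_fraction_max,gap_open,gap_extend Profile
#'   construction parameters (see [build_profile()]).
#' @param n_shuffles Null sample size per calibration.
#' @param seed Master seed (per-round calibration seeds are split from it).
#' @return Tibble as [profile_search()] plus a `round` column (first round
#'   of discovery). Zero hits in round 1 returns an empty tibble with a
#'   warning.
#' @export
iterative_search <- function(seed_msa, proteome, rounds = 2,
                             evalue_max = 0.01, pseudocount = 1,
                             gap_fraction_max = 0.5, gap_open = -11,
                             gap_extend = -1, n_shuffles = 500, seed = 1) {
  stopifnot(rounds >= 1)
  proteome <- as_proteome(proteome)
  lens <- nchar(proteome$seq)
  profile <- build_profile(seed_msa, pseudocount, gap_fraction_max,
                           gap_open = gap_open, gap_extend = gap_extend)
  found <- tibble(target_id = character(), score = numeric(),
                  evalue = numeric(), span_start = integer(),
                  span_end = integer(), round = integer())
  for (r in seq_len(rounds)) {
    profile <- calibrate_evalue(profile, n_shuffles = n_shuffles,
                                target_lengths = lens,
                                db_size = nrow(proteome),
                                seed = split_seed(seed, r))
    hits <- profile_search(profile, proteome, evalue_max)
    if (r == 1 && nrow(hits) == 0) {
      warning("no hits in round 1; returning empty candidate set")
      return(found)
    }
    new <- hits |>
      dplyr::filter(!.data$target_id %in% found$target_id) |>
      dplyr::mutate(round = as.integer(r))
    found <- dplyr::bind_rows(found, new)
    if (r < rounds) {
      msa_mat <- stack_hits(profile, proteome, found$target_id)
      profile <- build_profile(matrix_msa(msa_mat), pseudocount,
                               gap_fraction_max, gap_open = gap_open,
                               gap_extend = gap_extend)
    }
  }
  dplyr::arrange(found, .data$round, .data$evalue, .data$target_id)
}
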