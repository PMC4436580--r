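# Position-specific scoring model built from a seed family alignment, and
# local alignment of target proteins against it. This is the retrieval
# engine of the family mining pipeline: a PSSM with affine-gap local
# dynamic programming, scored in bits against a background distribution.

#' Build a position-specific scoring model from a seed alignment
#'
#' Alignment columns whose gap fraction exceeds `gap_fraction_max` are
#' excluded from match states. For a retained column c and residue a the
#' score is
#' `log2( (count_c(a) + pseudocount * bg(a)) / (total_c + pseudocount) / bg(a) )`
#' (background-proportional pseudocounts keep all scores finite).
#'
#' @param msa Alignment tibble from [read_msa()] (columns `id`, `seq`).
#' @param pseudocount Total pseudocount mass added per column (> 0).
#' @param gap_fraction_max Columns with a higher gap fraction become
#'   insert-only (excluded); in (0, 1].
#' @param background Amino-acid background probabilities (sum to 1);
#'   default uniform.
#' @param gap_open,gap_extend Affine gap penalties in bits (negative).
#' @return Object of class `pap_profile`.
#' @export
build_profile <- function(msa, pseudocount = 1, gap_fraction_max = 0.5,
                          background = uniform_background(),
                          gap_open = -11, gap_extend = -1) {
  stopifnot(pseudocount > 0, gap_fraction_max > 0, gap_fraction_max <= 1,
            abs(sum(background) - 1) < 1e-9,
            gap_open < 0, gap_extend < 0)
  m <- msa_matrix(msa)
  n_col <- ncol(m)
  gap_frac <- colMeans(m == "-")
  match_cols <- which(gap_frac <= gap_fraction_max)
  if (length(match_cols) == 0) {
    stop("no alignment columns retained as match states")
  }
  bg <- background[AA_ALPHABET]
  log_odds <- vapply(match_cols, function(j) {
    col <- m[, j]
    counts <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    total <- sum(counts)
    p <- (as.numeric(counts) + pseudocount * bg) / (total + pseudocount)
    log2(p / bg)
  }, numeric(20))
  log_odds <- matrix(log_odds, nrow = 20,
                     dimnames = list(AA_ALPHABET, as.character(match_cols)))
  structure(
    list(
      log_odds = log_odds,
      background = bg,
      gap_open = gap_open,
      gap_extend = gap_extend,
      n_match = length(match_cols),
      match_columns = match_cols,
      pseudocount = pseudocount,
      gap_fraction_max = gap_fraction_max,
      seed_match = m[, match_cols, drop = FALSE],
      evalue_model = NULL
    ),
    class = "pap_profile"
  )
}

#' @export
print.pap_profile <- function(x, ...) {
  cat("<profile model> ", x$n_match, " match columns from ",
      nrow(x$seed_match), " sequences; gap open/extend ",
      x$gap_open, "/", x$gap_extend, " bits; ",
      if (is.null(x$evalue_model)) "uncalibrated" else "E-value calibrated",
      "\n", sep = "")
  invisible(x)
}

encode_protein <- function(seq) {
  idx <- match(chars(toupper(seq)), AA_ALPHABET)
  idx[is.na(idx)] <- 0L          # unknown residues score 0 bits
  as.integer(idx)
}

#' Score a protein against a profile
#'
#' Best local alignment (affine gaps) of the sequence against the profile's
#' match columns by dynamic programming; the score is in bits and is never
#' negative (the empty alignment scores 0). Unknown residues (X, B, Z, U,
#' ...) score 0 bits at any column.
#'
#' @param profile A `pap_profile`.
#' @param seq Protein sequence string (non-empty).
#' @return List: `score` (bits), `span` (0-based half-open on the target),
#'   `col_pos` (per match column: 1-based target position, 0 = deleted
#'   column, -1 = outside the aligned span).
#' @export
score_sequence <- function(profile, seq) {
  stopifnot(nchar(seq) > 0)
  res <- profile_align_local(profile$log_odds, encode_protein(seq),
                             profile$gap_open, profile$gap_extend)
  list(score = res$score, span = c(res$start, res$end),
       col_pos = res$col_pos)
}

#' @rdname tidy.pap_profile
#' @export
glance.pap_profile <- function(x, ...) {
  tibble(
    n_match = x$n_match, n_seqs = nrow(x$seed_match),
    pseudocount = x$pseudocount, gap_fraction_max = x$gap_fraction_max,
    gap_open = x$gap_open, gap_extend = x$gap_extend,
    calibrated = !is.null(x$evalue_model)
  )
}

#' Tidiers for profile models
#'
#' `tidy()` returns the per-column log-odds in long form; `glance()` a
#' one-row model summary.
#'
#' @param x A `pap_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pap_profile <- function(x, ...) {
  tibble(
    column = rep(seq_len(x$n_match), each = 20),
    residue = rep(AA_ALPHABET, x$n_match),
    log_odds = as.vector(x$log_odds)
  )
}
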