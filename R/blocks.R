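# Conserved metal-binding block patterns and candidate validation.
#
# Plant purple acid phosphatases carry five short degenerate residue blocks,
# in fixed N-to-C order, whose fixed residues coordinate the di-metal centre.
# Family membership is defined by the presence of all five blocks in
# canonical order; candidates failing that filter are removed with a reason.

BLOCK_PRESETS <- list(
  gdxg = c(
    block1 = "GDXG",
    block2 = "GDXXY",
    block3 = "GNH(D/E)",
    block4 = "VXXH",
    block5 = "GHXH"
  ),
  # alternative first-block definition (DxG) in circulation for this family
  dxg = c(
    block1 = "DXG",
    block2 = "GDXXY",
    block3 = "GNH(D/E)",
    block4 = "VXXH",
    block5 = "GHXH"
  )
)

#' Compile degenerate block patterns
#'
#' Block patterns are written with residue letters, `X` for any residue, and
#' alternatives as `(D/E)` or `[DE]`. The default preset compiles the five
#' canonical purple-acid-phosphatase metal-binding blocks
#' `GDXG, GDXXY, GNH(D/E), VXXH, GHXH` (in canonical order). A second preset
#' `"dxg"` replaces the first block with the shorter `DXG` form.
#'
#' @param spec Character vector of pattern strings (optionally named), or a
#'   preset name: `"gdxg"` (default) or `"dxg"`.
#' @return A list of `pap_block_pattern` objects in the order given.
#' @export
#' @examples
#' pats <- compile_block_patterns()
#' pats[[3]]
compile_block_patterns <- function(spec = "gdxg") {
  if (length(spec) == 1 && spec %in% names(BLOCK_PRESETS)) {
    spec <- BLOCK_PRESETS[[spec]]
  }
  nm <- names(spec) %||% paste0("block", seq_along(spec))
  nm[nm == ""] <- paste0("block", which(nm == ""))
  out <- purrr::map2(spec, nm, compile_one_block)
  names(out) <- nm
  out
}

compile_one_block <- function(pattern, name) {
  cs <- chars(toupper(pattern))
  tokens <- list()
  i <- 1
  while (i <= length(cs)) {
    ch <- cs[i]
    if (ch == "X") {
      tokens <- c(tokens, list(AA_ALPHABET))
      i <- i + 1
    } else if (ch %in% AA_ALPHABET) {
      tokens <- c(tokens, list(ch))
      i <- i + 1
    } else if (ch %in% c("(", "[")) {
      close <- if (ch == "(") ")" else "]"
      j <- which(cs == close & seq_along(cs) > i)[1]
      if (is.na(j)) stop("malformed block pattern (unclosed bracket): ", pattern)
      inner <- setdiff(cs[(i + 1):(j - 1)], "/")
      if (length(inner) == 0 || !all(inner %in% AA_ALPHABET)) {
        stop("malformed block pattern (bad alternative set): ", pattern)
      }
      tokens <- c(tokens, list(inner))
      i <- j + 1
    } else {
      stop("malformed block pattern (invalid character '", ch, "'): ", pattern)
    }
  }
  if (length(tokens) == 0) stop("empty block pattern: ", pattern)
  if (!any(vapply(tokens, length, 1L) == 1)) {
    stop("block pattern must contain at least one fixed residue: ", pattern)
  }
  structure(
    list(name = name, tokens = tokens, length = length(tokens),
         string = pattern),
    class = "pap_block_pattern"
  )
}

#' @export
print.pap_block_pattern <- function(x, ...) {
  cat("<block pattern> ", x$name, ": ", render_block_pattern(x),
      " (length ", x$length, ")\n", sep = "")
  invisible(x)
}

#' Render a compiled block pattern back to its string form
#'
#' @param pattern A `pap_block_pattern`.
#' @return A pattern string; `compile -> render -> compile` is an identity on
#'   the token sets.
#' @export
render_block_pattern <- function(pattern) {
  paste(vapply(pattern$tokens, function(tok) {
    if (length(tok) == 20) "X"
    else if (length(tok) == 1) tok
    else paste0("(", paste(tok, collapse = "/"), ")")
  }, character(1)), collapse = "")
}

#' Find all occurrences of a block pattern in a protein sequence
#'
#' Reports every (possibly overlapping) start position at which all tokens
#' match. Coordinates are 0-based, half-open.
#'
#' @param seq Protein sequence string.
#' @param pattern A `pap_block_pattern`.
#' @return Tibble with columns `block`, `start`, `end`, sorted by `start`.
#' @export
#' @examples
#' pat <- compile_block_patterns()[[1]]
#' find_block_occurrences("AAGDAGAA", pat)
find_block_occurrences <- function(seq, pattern) {
  cs <- chars(toupper(seq))
  n <- length(cs)
  m <- pattern$length
  if (n < m) {
    return(tibble(block = character(), start = integer(), end = integer()))
  }
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    tok <- pattern$tokens[[j]]
    if (length(tok) < 20) {
      ok <- ok & (cs[seq(j, n - m + j)] %in% tok)
    }
  }
  starts <- which(ok) - 1L
  tibble(block = pattern$name, start = starts, end = starts + m)
}

# Greedy selection of one occurrence per block with strictly increasing,
# non-overlapping spans. Occurrences of a block all share one length, so the
# earliest feasible start is optimal (interval-scheduling exchange argument).
canonical_selection <- function(occ_by_block) {
  sel <- vector("list", length(occ_by_block))
  cursor <- 0L
  for (k in seq_along(occ_by_block)) {
    occ <- occ_by_block[[k]]
    feasible <- occ[occ$start >= cursor, , drop = FALSE]
    if (nrow(feasible) == 0) return(NULL)
    pick <- feasible[which.min(feasible$start), , drop = FALSE]
    sel[[k]] <- pick
    cursor <- pick$end
  }
  dplyr::bind_rows(sel)
}

#' Validate a candidate protein against the five conserved blocks
#'
#' A candidate is `valid` when one occurrence of each block can be selected
#' with strictly increasing starts and non-overlapping spans (canonical
#' order); `missing_blocks` when fewer than all blocks occur anywhere; and
#' `non_canonical` when all blocks occur but no ordered selection exists.
#'
#' @param seq Protein sequence string.
#' @param patterns List of compiled block patterns, in canonical order.
#' @param transcript_id Optional identifier carried into the report.
#' @return One-row tibble (class `pap_validation`) with columns
#'   `transcript_id`, `status`, `n_blocks_present`, and list-columns
#'   `blocks_present`, `occurrences`, `selection` (`NULL` unless valid).
#' @export
#' @examples
#' validate_blocks(generate_pap_protein(1)$seq)
validate_blocks <- function(seq, patterns = compile_block_patterns(),
                            transcript_id = NA_character_) {
  occ_by_block <- purrr::map(patterns, find_block_occurrences, seq = seq)
  occurrences <- dplyr::bind_rows(occ_by_block)
  present <- names(patterns)[vapply(occ_by_block, nrow, 1L) > 0]
  selection <- NULL
  if (length(present) == length(patterns)) {
    selection <- canonical_selection(occ_by_block)
    status <- if (is.null(selection)) "non_canonical" else "valid"
  } else {
    status <- "missing_blocks"
  }
  out <- tibble(
    transcript_id = transcript_id,
    status = status,
    n_blocks_present = length(present),
    blocks_present = list(present),
    occurrences = list(occurrences),
    selection = list(selection)
  )
  class(out) <- c("pap_validation", class(out))
  out
}

#' Choose the best splice model for a gene
#'
#' Mirrors curation practice: a gene whose primary transcript fails the
#' block filter is rescued if any alternative splice model encodes all five
#' blocks in canonical order. Valid transcripts win; ties prefer the primary
#' transcript, then the lexicographically smallest id. If no transcript is
#' valid, the one presenting the most blocks is chosen.
#'
#' @param transcripts Tibble with columns `transcript_id`, `seq` and
#'   (optionally) `is_primary`.
#' @param patterns Compiled block patterns in canonical order.
#' @return List with `chosen` (one-row `pap_validation`) and `reports`
#'   (validation rows for every transcript).
#' @export
select_best_transcript <- function(transcripts,
                                   patterns = compile_block_patterns()) {
  stopifnot(nrow(transcripts) >= 1)
  if (is.null(transcripts$is_primary)) transcripts$is_primary <- FALSE
  reports <- purrr::map2(
    transcripts$seq, transcripts$transcript_id,
    ~ validate_blocks(.x, patterns, transcript_id = .y)
  ) |> dplyr::bind_rows()
  ord <- order(
    reports$status != "valid",        # valid first
    -reports$n_blocks_present,        # then most blocks
    !transcripts$is_primary,          # then primary
    reports$transcript_id             # then id
  )
  list(chosen = reports[ord[1], ], reports = reports)
}

#' Apply the conserved-block curation filter to a candidate set
#'
#' Each gene is judged on its best splice model (see
#' [select_best_transcript()]); genes whose best transcript is not valid are
#' removed with the failure status as the removal reason.
#'
#' @param candidates Tibble with columns `gene_id`, `transcript_id`, `seq`
#'   and optionally `is_primary`.
#' @param patterns Compiled block patterns in canonical order.
#' @return Tibble with one row per gene: `gene_id`, `transcript_id` (the
#'   chosen model), `status`, `kept` (logical), `reason` (`NA` for kept
#'   genes), `n_blocks_present`.
#' @export
#' @examples
#' cands <- generate_candidate_set(seed = 7)
#' dplyr::count(filter_candidates(cands), kept, reason)
filter_candidates <- function(candidates,
                              patterns = compile_block_patterns()) {
  if (nrow(candidates) == 0) {
    return(tibble(
      gene_id = character(), transcript_id = character(),
      status = character(), kept = logical(), reason = character(),
      n_blocks_present = integer()
    ))
  }
  candidates |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      chosen <- select_best_transcript(df, patterns)$chosen
      tibble(
        transcript_id = chosen$transcript_id,
        status = chosen$status,
        kept = chosen$status == "valid",
        reason = ifelse(chosen$status == "valid", NA_character_,
                        chosen$status),
        n_blocks_present = chosen$n_blocks_present
      )
    }) |>
    dplyr::ungroup()
}
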