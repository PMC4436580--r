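# P1BS cis-element scanning in upstream regions.
#
# The PHR1 transcription factor, master regulator of the phosphate
# starvation response, binds the imperfect palindromic element GNATATNC
# (P1BS). Because the element's consensus equals its own reverse
# complement, a physical site matching on the minus strand also matches the
# consensus on the plus strand; each location is reported once.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Parse an IUPAC DNA motif
#'
#' @param motif_string Motif written with IUPAC ambiguity codes, e.g.
#'   `"GNATATNC"` for the P1BS element.
#' @return Object of class `pap_motif`: per-position base sets and length.
#' @export
#' @examples
#' parse_iupac("GNATATNC")
parse_iupac <- function(motif_string) {
  cs <- chars(toupper(motif_string))
  bad <- setdiff(cs, names(IUPAC_DNA))
  if (length(cs) == 0 || length(bad) > 0) {
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(string = toupper(motif_string), sets = IUPAC_DNA[cs],
         length = length(cs)),
    class = "pap_motif"
  )
}

#' @export
print.pap_motif <- function(x, ...) {
  cat("<IUPAC motif> ", x$string, " (length ", x$length, ", ",
      prod(vapply(x$sets, length, 1L)), " matching words)\n", sep = "")
  invisible(x)
}

# The base sets a word must satisfy position-wise for its reverse complement
# to match the motif.
revcomp_sets <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lapply(rev(motif$sets), function(s) unname(comp[s]))
}

match_positions <- function(cs, sets) {
  n <- length(cs)
  m <- length(sets)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & (cs[seq(j, n - m + j)] %in% sets[[j]])
  }
  which(ok)
}

#' Scan upstream sequences for a cis-element
#'
#' Scans both strands of each upstream sequence for the motif. Offsets give
#' the position of the match's 5'-most base relative to the gene anchor,
#' rendered as a negative integer (-1 is the base immediately before the
#' anchor; the sequence 3' end sits at -1). A location matching on both
#' strands -- the generic case for the self-reverse-complementary P1BS
#' consensus -- is reported once, with strand `+`. Ambiguous `N` bases in
#' the sequence match nothing. Matches are sorted by gene and ascending
#' offset (most distal first).
#'
#' @param upstream Tibble with columns `gene_id` and `seq` (see
#'   [extract_upstream()] / [generate_upstream_set()]), or a single string.
#' @param motif A `pap_motif`; default is the P1BS element `GNATATNC`.
#' @return Tibble with columns `gene_id`, `offset`, `strand`, `word`.
#' @export
#' @examples
#' up <- generate_upstream_set(planted = list(g1 = c(-232, -2463)), seed = 1)
#' scan_p1bs(up$sequences)
scan_p1bs <- function(upstream, motif = parse_iupac("GNATATNC")) {
  if (is.character(upstream)) {
    upstream <- tibble(gene_id = "seq1", seq = upstream)
  }
  rc_sets <- revcomp_sets(motif)
  purrr::map2(upstream$gene_id, upstream$seq, function(gid, s) {
    cs <- chars(toupper(s))
    n <- length(cs)
    plus <- match_positions(cs, motif$sets)
    minus <- match_positions(cs, rc_sets)
    idx <- sort(union(plus, minus))
    if (length(idx) == 0) {
      return(tibble(gene_id = character(), offset = integer(),
                    strand = character(), word = character()))
    }
    tibble(
      gene_id = gid,
      offset = as.integer(idx - n - 1L),
      strand = ifelse(idx %in% plus, "+", "-"),
      word = vapply(idx, function(i) paste(cs[i:(i + motif$length - 1)],
                                           collapse = ""), character(1))
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$gene_id, .data$offset)
}

#' Extract upstream windows from a genome
#'
#' For plus-strand genes the window covers `[anchor - window, anchor - 1]`
#' on the plus strand (0-based genome coordinates, `anchor` being the
#' position of the first translated/transcribed base); for minus-strand
#' genes, the reverse complement of `[anchor + 1, anchor + window]`.
#' Windows are truncated at contig edges.
#'
#' @param genome Named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param anchors Tibble with columns `gene_id`, `chrom`, `anchor_pos`
#'   (0-based position of the anchor base) and `strand` (`+`/`-`).
#' @param gene_ids Genes to extract (default: all rows of `anchors`).
#' @param window Window width in bp (default 2500).
#' @param anchor Which anchor the coordinates represent; carried as
#'   metadata. The published per-gene locations follow the translational
#'   start, while the scan was described against the transcriptional start;
#'   both are supported and neither is silently assumed.
#' @return Tibble: `gene_id`, `seq`, `window`, `anchor`, `strand`, `length`.
#' @export
extract_upstream <- function(genome, anchors, gene_ids = anchors$gene_id,
                             window = 2500,
                             anchor = c("translational_start",
                                        "transcriptional_start")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 1)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(gene_ids, anchors$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) not found in annotation: ", paste(missing, collapse = ", "))
  }
  rows <- anchors[match(gene_ids, anchors$gene_id), ]
  purrr::pmap(rows[c("gene_id", "chrom", "anchor_pos", "strand")],
              function(gene_id, chrom, anchor_pos, strand) {
    if (!chrom %in% names(genome)) stop("contig not found: ", chrom)
    contig <- genome[[chrom]]
    len <- nchar(contig)
    if (strand == "+") {
      from <- max(0, anchor_pos - window)     # 0-based inclusive
      to <- anchor_pos                        # 0-based exclusive
      s <- substr(contig, from + 1, to)
    } else {
      from <- anchor_pos + 1
      to <- min(len, anchor_pos + 1 + window)
      s <- revcomp(substr(contig, from + 1, to))
    }
    tibble(gene_id = gene_id, seq = toupper(s), window = window,
           anchor = anchor, strand = strand, length = nchar(s))
  }) |> dplyr::bind_rows()
}

#' Tabulate cis-element matches per gene
#'
#' Produces the per-gene presentation used for published P1BS tables: one
#' row per gene (zero-count genes included), the match count, and the list
#' of signed locations ordered proximal-first (ascending distance from the
#' anchor).
#'
#' @param matches Output of [scan_p1bs()].
#' @param genes Character vector of all gene ids to report (supplies the
#'   zero-count rows).
#' @return Tibble (class `pap_p1bs`) with columns `gene_id`, `p1bs_count`,
#'   `locations` (list of integers, proximal first), `location_str`.
#' @export
tabulate_p1bs <- function(matches, genes) {
  per_gene <- matches |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      p1bs_count = dplyr::n(),
      locations = list(.data$offset[order(abs(.data$offset))])
    )
  out <- tibble(gene_id = as.character(genes)) |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      p1bs_count = ifelse(is.na(.data$p1bs_count), 0L,
                          as.integer(.data$p1bs_count)),
      locations = purrr::map(.data$locations, ~ .x %||% integer(0)),
      location_str = purrr::map_chr(.data$locations, paste, collapse = ", ")
    )
  class(out) <- c("pap_p1bs", class(out))
  out
}

#' Summarize a per-gene cis-element table
#'
#' @param table A `pap_p1bs` table from [tabulate_p1bs()] (or the packaged
#'   reference table; any tibble with `p1bs_count` and `locations`).
#' @param proximal_window Distance (bp) defining a proximal site.
#' @return One-row tibble: `n_genes`, `n_with_any`, `n_with_proximal`.
#' @export
#' @examples
#' summarize_p1bs(read_p1bs_reference())
summarize_p1bs <- function(table, proximal_window = 1000) {
  tibble(
    n_genes = nrow(table),
    n_with_any = sum(table$p1bs_count >= 1),
    n_with_proximal = sum(purrr::map_lgl(
      table$locations, ~ any(.x >= -proximal_window & .x <= -1)
    ))
  )
}
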