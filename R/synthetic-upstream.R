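# Seeded generator for upstream DNA with planted cis-elements.

instantiate_motif_word <- function(motif) {
  paste(vapply(motif$sets, function(s) sample(s, 1), character(1)),
        collapse = "")
}

#' Generate upstream sequences with planted P1BS sites
#'
#' Builds one upstream window per gene over a uniform ACGT background, with
#' motif instances planted at known offsets and strands. The background is
#' cleaned by rejection: any spurious motif match (either strand) outside
#' the planted spans is destroyed by resampling one of its bases, so the
#' scanner's ground truth is exact. Planted offsets are positions of the
#' site's 5'-most base relative to the anchor (negative; the window's 3'
#' end is at -1).
#'
#' @param n_genes Number of genes; defaults to the genes named in `planted`.
#' @param planted Named list, `gene_id -> integer offsets` (plus strand) or
#'   a tibble per gene with columns `offset` and `strand`. Genes without an
#'   entry get no sites.
#' @param window Window width in bp (default 2500).
#' @param motif A `pap_motif` (default P1BS, `GNATATNC`).
#' @param seed Master seed.
#' @return List with `sequences` (tibble `gene_id`, `seq`, `window`,
#'   `anchor`, `length`) and `truth` (tibble `gene_id`, `offset`, `strand`,
#'   `word`).
#' @export
#' @examples
#' up <- generate_upstream_set(planted = list(g1 = c(-232, -2463)), seed = 1)
#' up$truth
generate_upstream_set <- function(n_genes = NULL, planted = list(),
                                  window = 2500,
                                  motif = parse_iupac("GNATATNC"),
                                  seed = 1) {
  gene_ids <- names(planted)
  if (!is.null(n_genes) && n_genes > length(gene_ids)) {
    extra <- sprintf("SYNUP%04d", seq_len(n_genes - length(gene_ids)))
    gene_ids <- c(gene_ids, extra)
  }
  m <- motif$length
  rc_sets <- revcomp_sets(motif)

  with_seed(seed, {
    rows <- purrr::map(gene_ids, function(gid) {
      plant <- planted[[gid]]
      if (is.null(plant)) {
        plant <- tibble(offset = integer(0), strand = character(0))
      } else if (!is.data.frame(plant)) {
        plant <- tibble(offset = as.integer(plant), strand = "+")
      }
      if (any(plant$offset < -window | plant$offset > -m)) {
        stop("planted offsets must lie in [-window, -motif length]")
      }
      idx <- plant$offset + window + 1L   # 1-based start index in the window
      if (nrow(plant) > 1) {
        o <- order(idx)
        if (any(diff(idx[o]) < m)) {
          stop("overlapping planted motifs for gene ", gid,
               " (ambiguous truth)")
        }
      }
      cs <- sample(DNA_BASES, window, replace = TRUE)
      words <- character(nrow(plant))
      for (k in seq_len(nrow(plant))) {
        w <- instantiate_motif_word(motif)
        if (plant$strand[k] == "-") w <- revcomp(w)
        words[k] <- w
        cs[idx[k]:(idx[k] + m - 1)] <- chars(w)
      }
      planted_span <- unlist(purrr::map(idx, ~ seq(.x, .x + m - 1)))

      # destroy spurious matches without touching planted spans
      spurious_at <- function(cs) {
        hits <- sort(union(match_positions(cs, motif$sets),
                           match_positions(cs, rc_sets)))
        setdiff(hits, idx)
      }
      for (iter in 1:200) {
        spurious <- spurious_at(cs)
        if (length(spurious) == 0) break
        for (i in spurious) {
          span <- setdiff(seq(i, i + m - 1), planted_span)
          j <- if (length(span) == 1) span else sample(span, 1)
          cs[j] <- sample(setdiff(DNA_BASES, cs[j]), 1)
        }
      }
      if (length(spurious_at(cs)) > 0) {
        stop("failed to clean spurious motif matches")
      }

      list(
        sequence = tibble(gene_id = gid, seq = paste(cs, collapse = ""),
                          window = window, anchor = "translational_start",
                          length = window),
        truth = tibble(gene_id = gid, offset = plant$offset,
                       strand = plant$strand, word = words)
      )
    })
    list(
      sequences = dplyr::bind_rows(purrr::map(rows, "sequence")),
      truth = dplyr::bind_rows(purrr::map(rows, "truth")) |>
        dplyr::arrange(.data$gene_id, .data$offset)
    )
  })
}
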