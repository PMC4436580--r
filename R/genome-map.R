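# Physical-map co-localization of family gene loci with QTL and isozyme
# intervals. All coordinates are 0-based half-open internally (BED
# semantics).

#' Read genomic intervals from BED or TSV
#'
#' BED input (no header; columns chrom, start, end, name, ...) keeps its
#' native 0-based half-open coordinates. The TSV dialect has a header with
#' columns `chrom`, `start`, `end`, `label` and optionally `kind`, also
#' 0-based half-open.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @param kind Interval kind recorded in the result when the file carries
#'   none (`gene`, `qtl` or `isozyme`).
#' @return Tibble: `chrom`, `start`, `end`, `label`, `kind`.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "tsv"),
                           kind = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = "c"))
    stopifnot(ncol(raw) >= 3)
    out <- tibble(
      chrom = raw[[1]],
      start = as.numeric(raw[[2]]),
      end = as.numeric(raw[[3]]),
      label = if (ncol(raw) >= 4) raw[[4]] else
        sprintf("iv%04d", seq_len(nrow(raw))),
      kind = kind
    )
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols())
    stopifnot(all(c("chrom", "start", "end", "label") %in% names(raw)))
    out <- tibble(
      chrom = as.character(raw$chrom),
      start = as.numeric(raw$start),
      end = as.numeric(raw$end),
      label = as.character(raw$label),
      kind = if ("kind" %in% names(raw)) as.character(raw$kind) else kind
    )
  }
  validate_intervals(out)
  out
}

validate_intervals <- function(x) {
  if (any(!nzchar(x$chrom))) stop("empty chromosome name")
  if (any(x$start >= x$end)) {
    stop("invalid interval: start must be < end (0-based half-open)")
  }
  invisible(x)
}

#' Write intervals to BED
#'
#' @param x Interval tibble (see [read_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  readr::write_tsv(
    dplyr::select(x, "chrom", "start", "end", "label"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Co-localize gene loci with genomic features
#'
#' Classifies each gene/feature pair on the same chromosome as `within`
#' (gene interval contained in the feature), `overlaps` (non-empty
#' intersection), or `proximal` (disjoint with a gap of at most `slop`
#' bp). Pairs farther apart are not reported.
#'
#' @param genes,features Interval tibbles (`chrom`, `start`, `end`,
#'   `label`; 0-based half-open).
#' @param slop Maximum gap (bp) for a `proximal` call; `"close to"` a QTL
#'   defaults to 1 Mb.
#' @return Tibble: `gene`, `feature`, `chrom`, `relation`, `gap` (0 unless
#'   proximal).
#' @export
#' @examples
#' genes <- tibble::tibble(chrom = "chr10", start = 5, end = 6, label = "g")
#' qtl <- tibble::tibble(chrom = "chr10", start = 4, end = 8, label = "Q")
#' colocalize(genes, qtl)
colocalize <- function(genes, features, slop = 1e6) {
  stopifnot(slop >= 0)
  validate_intervals(genes)
  validate_intervals(features)
  chroms <- union(genes$chrom, features$chrom)
  gr_g <- GenomicRanges::GRanges(
    factor(genes$chrom, chroms),
    IRanges::IRanges(genes$start + 1, genes$end)
  )
  gr_f <- GenomicRanges::GRanges(
    factor(features$chrom, chroms),
    IRanges::IRanges(features$start + 1, features$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_g, gr_f, maxgap = slop)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    return(tibble(gene = character(), feature = character(),
                  chrom = character(), relation = character(),
                  gap = numeric()))
  }
  gs <- genes$start[qi]; ge <- genes$end[qi]
  fs <- features$start[si]; fe <- features$end[si]
  gap <- pmax(gs - fe, fs - ge, 0)
  relation <- dplyr::case_when(
    gs >= fs & ge <= fe ~ "within",
    gap == 0 & (pmin(ge, fe) > pmax(gs, fs)) ~ "overlaps",
    TRUE ~ "proximal"
  )
  out <- tibble(
    gene = genes$label[qi], feature = features$label[si],
    chrom = genes$chrom[qi], relation = relation, gap = gap
  )
  # adjacency (gap 0, empty intersection) counts as proximal, not overlap
  dplyr::filter(out, !(.data$relation == "proximal" & .data$gap > slop)) |>
    dplyr::arrange(.data$gene, .data$feature)
}
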