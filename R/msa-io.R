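# Reading multiple sequence alignments (FASTA / Stockholm).

#' Read a protein multiple sequence alignment
#'
#' Supports aligned FASTA (via Biostrings) and single- or multi-block
#' Stockholm 1.0. Gap characters `-` and `.` are normalized to `-`;
#' residues are upper-cased. Errors on ragged alignments, empty files, or
#' fewer than two records.
#'
#' @param path File path.
#' @param format `"auto"` (default; Stockholm header or file extension
#'   decides), `"fasta"` or `"stockholm"`.
#' @return Tibble with columns `id`, `seq` (equal-length aligned strings);
#'   attribute `n_columns` gives the alignment width.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (length(first) > 0 && grepl("^# STOCKHOLM", first)) {
      "stockholm"
    } else if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE)) {
      "stockholm"
    } else {
      "fasta"
    }
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    msa <- tibble(id = sub("\\s.*$", "", names(set)),
                  seq = unname(as.character(set)))
  } else {
    msa <- read_stockholm(path)
  }
  msa$seq <- toupper(gsub(".", "-", msa$seq, fixed = TRUE))
  if (nrow(msa) < 2) stop("alignment must contain at least two sequences")
  widths <- nchar(msa$seq)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: sequences differ in length")
  }
  attr(msa, "n_columns") <- widths[1]
  msa
}

# Minimal Stockholm 1.0 parser: concatenates sequence lines per id across
# blocks, ignores annotation (#=...) and comment lines, stops at '//'.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty Stockholm file: ", path)
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (grepl("^//", ln)) break
    if (grepl("^#", ln) || grepl("^\\s*$", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed Stockholm line: ", ln)
    id <- parts[1]
    if (!id %in% order) order <- c(order, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2])
  }
  if (length(seqs) == 0) stop("no sequences found in Stockholm file: ", path)
  tibble(id = order, seq = unlist(seqs[order], use.names = FALSE))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id`/`seq` columns (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  id_col <- intersect(c("id", "record_id", "gene_id", "transcript_id"),
                      names(x))[1]
  set <- Biostrings::BStringSet(setNames(x$seq, x[[id_col]]))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# alignment tibble -> character matrix (rows = sequences)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seq, "", fixed = TRUE))
  rownames(m) <- msa$id
  m
}

matrix_msa <- function(m) {
  tibble(id = rownames(m), seq = apply(m, 1, paste, collapse = ""))
}
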