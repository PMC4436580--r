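# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each result by exhaustive enumeration or a
# naive algorithm, sharing no code path with the package internals.

# -- block validation ---------------------------------------------------

# all (possibly overlapping) matches of a token list, position by position
naive_find_occurrences <- function(seq, pattern) {
  cs <- strsplit(toupper(seq), "")[[1]]
  m <- pattern$length
  starts <- integer(0)
  for (i in seq_len(max(0, length(cs) - m + 1))) {
    hit <- TRUE
    for (j in seq_len(m)) {
      if (!cs[i + j - 1] %in% pattern$tokens[[j]]) { hit <- FALSE; break }
    }
    if (hit) starts <- c(starts, i - 1L)
  }
  starts
}

# enumerate ALL tuples of one occurrence per block and test for an ordered,
# non-overlapping selection
brute_validate <- function(seq, patterns) {
  occ <- lapply(patterns, function(p) naive_find_occurrences(seq, p))
  lens <- vapply(patterns, function(p) p$length, 1L)
  present <- sum(vapply(occ, length, 1L) > 0)
  if (present < length(patterns)) return("missing_blocks")
  grid <- expand.grid(occ, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    starts <- as.numeric(grid[r, ])
    ends <- starts + lens
    if (all(diff(starts) > 0) && all(starts[-1] >= ends[-length(ends)])) {
      return("valid")
    }
  }
  "non_canonical"
}

# random protein enriched with block words so that all validation statuses
# are exercised
block_enriched_protein <- function(len, patterns) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  cs <- sample(aa, len, replace = TRUE)
  n_inserts <- sample(0:6, 1)
  for (k in seq_len(n_inserts)) {
    p <- patterns[[sample(length(patterns), 1)]]
    word <- vapply(p$tokens, function(tok) tok[sample.int(length(tok), 1)],
                   character(1))
    pos <- sample(len - p$length, 1)
    cs[pos:(pos + p$length - 1)] <- word
  }
  paste(cs, collapse = "")
}

# -- profile alignment --------------------------------------------------

# exhaustive enumeration of every local alignment path (start/end in match
# state, affine gap costs) for tiny instances
brute_local_align <- function(log_odds, seq_idx, gap_open, gap_extend) {
  M <- ncol(log_odds)
  L <- length(seq_idx)
  sc <- function(i, j) {
    a <- seq_idx[j]
    if (a > 0) log_odds[a, i] else 0
  }
  best <- 0
  recurse <- function(i, j, state, score) {
    if (state == "M") best <<- max(best, score)
    if (i < M && j < L) {
      recurse(i + 1, j + 1, "M", score + sc(i + 1, j + 1))
    }
    if (i < M) {  # delete a profile column
      cost <- if (state == "D") gap_extend else gap_open
      recurse(i + 1, j, "D", score + cost)
    }
    if (j < L) {  # insert a sequence residue
      cost <- if (state == "I") gap_extend else gap_open
      recurse(i, j + 1, "I", score + cost)
    }
  }
  for (i in seq_len(M)) {
    for (j in seq_len(L)) {
      recurse(i, j, "M", sc(i, j))
    }
  }
  best
}

# -- motif scanning -----------------------------------------------------

# regex-based overlap-aware scanner for GNATATNC on both strands
naive_scan_gnatatnc <- function(seq) {
  rx <- "(?=G[ACGT]ATAT[ACGT]C)"
  hit_starts <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  n <- nchar(seq)
  plus <- hit_starts(seq)
  rc <- papfam::revcomp(seq)
  minus_rc <- hit_starts(rc)
  minus <- sort((n - 8 + 1) - minus_rc + 1)  # map back to plus coordinates
  sort(union(plus, minus))
}

# -- intervals ----------------------------------------------------------

# quadratic all-pairs co-localization classifier
brute_colocalize <- function(genes, features, slop) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(features))) {
      if (genes$chrom[i] != features$chrom[j]) next
      gs <- genes$start[i]; ge <- genes$end[i]
      fs <- features$start[j]; fe <- features$end[j]
      inter <- min(ge, fe) - max(gs, fs)
      gap <- max(gs - fe, fs - ge, 0)
      rel <- if (gs >= fs && ge <= fe) "within"
      else if (inter > 0) "overlaps"
      else if (gap <= slop) "proximal"
      else NA_character_
      if (!is.na(rel)) {
        out[[length(out) + 1]] <- data.frame(
          gene = genes$label[i], feature = features$label[j],
          relation = rel, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), feature = character(),
                      relation = character())
  }
  res[order(res$gene, res$feature), , drop = FALSE]
}

# -- counts -------------------------------------------------------------

# binomial-split p-value for the phi = 0 exact test, by full enumeration
brute_binomial_p <- function(s1, s2, n1, n2) {
  t <- s1 + s2
  pr <- dbinom(0:t, t, n1 / (n1 + n2))
  sum(pr[pr <= pr[s1 + 1] * (1 + 1e-8)])
}

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  tr
}
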