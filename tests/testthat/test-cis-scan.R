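# IUPAC motif parsing, upstream extraction, P1BS scanning and tabulation.

test_that("IUPAC parsing expands ambiguity codes", {
  m <- parse_iupac("GNATATNC")
  expect_equal(m$length, 8)
  expect_equal(sort(m$sets[[2]]), c("A", "C", "G", "T"))
  expect_equal(sort(m$sets[[7]]), c("A", "C", "G", "T"))
  expect_equal(m$sets[[1]], "G")

  simple <- parse_iupac("ACGT")
  expect_true(all(lengths(simple$sets) == 1))

  expect_error(parse_iupac("GQAT"), "invalid IUPAC")
})

test_that("exactly 16 of the 65536 8-mers match the P1BS consensus", {
  m <- parse_iupac("GNATATNC")
  words <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 8),
                                       stringsAsFactors = FALSE))
  n_match <- sum(vapply(words, function(w) {
    cs <- strsplit(w, "")[[1]]
    all(vapply(seq_len(8), function(j) cs[j] %in% m$sets[[j]], logical(1)))
  }, logical(1)))
  expect_equal(n_match, 16)
})

test_that("scanning agrees with a naive both-strand regex oracle", {
  withr::with_seed(21, {
    for (i in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
      mine <- scan_p1bs(tibble::tibble(gene_id = "g", seq = s))
      expect_equal(as.integer(mine$offset + 3000 + 1),
                   naive_scan_gnatatnc(s))
      # palindrome dedup: offsets unique
      expect_equal(anyDuplicated(mine$offset), 0)
    }
  })
})

test_that("scanning matches an established pattern matcher", {
  withr::with_seed(22, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
      mine <- scan_p1bs(tibble::tibble(gene_id = "g", seq = s))
      subj <- Biostrings::DNAString(s)
      fwd <- Biostrings::start(Biostrings::matchPattern(
        "GNATATNC", subj, fixed = "subject"))
      rev <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(Biostrings::DNAString("GNATATNC")),
        subj, fixed = "subject"))
      expect_equal(as.integer(mine$offset + 3000 + 1),
                   sort(union(fwd, rev)))
    }
  })
})

test_that("planted sites are recovered perfectly and Ns match nothing", {
  planted <- withr::with_seed(23, {
    n <- 120
    setNames(lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(integer(0))
      sort(sample(seq(-2500, -8), k))
    }), sprintf("G%03d", seq_len(120)))
  })
  # reject plants closer than a motif length apart
  planted <- lapply(planted, function(off) {
    if (length(off) < 2) off else off[c(TRUE, diff(off) >= 8)]
  })
  up <- generate_upstream_set(planted = planted, window = 2500, seed = 24)
  hits <- scan_p1bs(up$sequences)
  got <- dplyr::arrange(hits[c("gene_id", "offset")], gene_id, offset)
  want <- dplyr::arrange(up$truth[c("gene_id", "offset")], gene_id, offset)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$offset, want$offset)

  # offsets always within the window
  expect_true(all(hits$offset >= -2500 & hits$offset <= -8))

  # N in the sequence matches nothing, even at motif N positions
  expect_equal(nrow(scan_p1bs("GNATATNC")), 0)
  expect_equal(nrow(scan_p1bs(strrep("A", 100))), 0)
  expect_equal(nrow(scan_p1bs(paste0(strrep("A", 50), "GAATATAC"))), 1)
})

test_that("upstream extraction follows strand-aware coordinates", {
  withr::with_seed(25, {
    contig <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                    collapse = "")
  })
  genome <- c(chr1 = contig)
  anchors <- tibble::tibble(
    gene_id = c("gp", "gm", "gedge"),
    chrom = "chr1",
    anchor_pos = c(3000L, 1000L, 100L),
    strand = c("+", "-", "+")
  )
  up <- extract_upstream(genome, anchors, window = 2500)
  # plus strand: bases 500..2999 (0-based)
  expect_equal(up$seq[1], substr(contig, 501, 3000))
  # minus strand: reverse complement of [anchor+1, anchor+window]
  expect_equal(up$seq[2], revcomp(substr(contig, 1002, 3501)))
  # truncated at contig start
  expect_equal(up$length[3], 100L)
  expect_equal(up$seq[3], substr(contig, 1, 100))
  expect_error(extract_upstream(genome, anchors, gene_ids = "nope"),
               "not found")

  # a site planted on the minus-strand gene is recovered at the same
  # signed offset after extraction
  word <- "GAATATAC"
  # for the minus-strand gene, offset -300 means window position 2201
  # (1-based) of the reverse complement; plant accordingly on the genome
  up_m <- up$seq[2]
  planted <- paste0(substr(up_m, 1, 2500 - 300), word,
                    substr(up_m, 2500 - 300 + 8 + 1, 2500))
  genome2 <- c(chr1 = paste0(
    substr(contig, 1, 1001), revcomp(planted), substr(contig, 3502, 5000)
  ))
  up2 <- extract_upstream(genome2, anchors, gene_ids = "gm", window = 2500)
  hits <- scan_p1bs(up2)
  expect_true(-300 %in% hits$offset)
})

test_that("tabulation mirrors the published per-gene presentation", {
  up <- generate_upstream_set(
    planted = list(ZmPap10 = c(-232L, -2463L)), n_genes = 3, seed = 26
  )
  tab <- tabulate_p1bs(scan_p1bs(up$sequences), up$sequences$gene_id)
  expect_equal(nrow(tab), 3)
  r10 <- tab[tab$gene_id == "ZmPap10", ]
  expect_equal(r10$p1bs_count, 2L)
  # proximal first
  expect_equal(r10$locations[[1]], c(-232L, -2463L))
  expect_equal(r10$location_str, "-232, -2463")
  # zero-count genes present with empty locations
  expect_true(all(tab$p1bs_count == lengths(tab$locations)))
  expect_equal(sum(tab$p1bs_count == 0), 2)
})

test_that("summaries count genes with any and with proximal sites", {
  ref <- read_p1bs_reference()
  s <- summarize_p1bs(ref)
  expect_equal(s$n_with_any, 19)
  expect_equal(s$n_genes, 33)
  # with the proximal window widened to the full survey window the two
  # counts coincide
  s2 <- summarize_p1bs(ref, proximal_window = 2500)
  expect_equal(s2$n_with_proximal, s2$n_with_any)
  # empty table
  empty <- tabulate_p1bs(
    tibble::tibble(gene_id = character(), offset = integer(),
                   strand = character(), word = character()),
    character(0)
  )
  s0 <- summarize_p1bs(empty)
  expect_equal(c(s0$n_with_any, s0$n_with_proximal), c(0L, 0L))
})
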