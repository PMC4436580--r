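# Profile construction, local DP scoring, E-value calibration, and the
# one- and two-round searches.

toy_msa <- function(seqs) tibble::tibble(id = paste0("s", seq_along(seqs)),
                                         seq = seqs)

test_that("alignment reading normalizes dialects and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "AC-DE", ">b", "acgde"), fa)
  msa <- read_msa(fa)
  expect_equal(msa$id, c("a", "b"))
  expect_equal(msa$seq, c("AC-DE", "ACGDE"))
  expect_equal(attr(msa, "n_columns"), 5)

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID toy", "a AC.DE", "b ACGDE", "//"),
             sto)
  msa2 <- read_msa(sto)
  expect_equal(msa2$seq, msa$seq)

  ragged <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACDE", ">b", "ACD"), ragged)
  expect_error(read_msa(ragged), "ragged")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_msa(empty))
})

test_that("profile log-odds follow the closed form", {
  # single conserved column, tiny pseudocount: log-odds(A) -> log2(20)
  prof <- build_profile(toy_msa(c("A", "A")), pseudocount = 1e-9)
  expect_equal(prof$log_odds["A", 1], log2(20), tolerance = 1e-6)

  # all-gap column excluded from match states
  prof2 <- build_profile(toy_msa(c("A-C", "A-C")))
  expect_equal(prof2$n_match, 2)
  expect_equal(prof2$match_columns, c(1L, 3L))

  # huge pseudocount: every log-odds tends to 0
  prof3 <- build_profile(toy_msa(c("AC", "AC")), pseudocount = 1e9)
  expect_lt(max(abs(prof3$log_odds)), 1e-6)

  expect_error(build_profile(toy_msa(c("--", "--"))), "no alignment columns")
})

test_that("consensus sequence scores the sum of per-column maxima", {
  msa <- dplyr::bind_rows(lapply(1:6, function(i)
    generate_pap_protein(500 + i, spacing = c(6, 6))))
  prof <- build_profile(toy_msa(msa$seq))
  cons <- paste(rownames(prof$log_odds)[apply(prof$log_odds, 2, which.max)],
                collapse = "")
  expect_equal(score_sequence(prof, cons)$score,
               sum(apply(prof$log_odds, 2, max)), tolerance = 1e-9)
})

test_that("DP local score equals the exhaustive alignment oracle", {
  withr::with_seed(11, {
    for (i in 1:300) {
      n_col <- sample(1:3, 1)
      n_seq <- sample(1:4, 1)
      msa <- toy_msa(replicate(3, paste(sample(c("A", "C", "D", "G"), n_col,
        replace = TRUE), collapse = "")))
      prof <- build_profile(msa, gap_open = -3, gap_extend = -1)
      target <- paste(sample(c("A", "C", "D", "G", "X"), n_seq,
                             replace = TRUE), collapse = "")
      got <- score_sequence(prof, target)$score
      want <- brute_local_align(prof$log_odds, papfam:::encode_protein(target),
                                -3, -1)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("local score never decreases when unrelated flanks are appended", {
  fam <- dplyr::bind_rows(lapply(1:5, function(i)
    generate_pap_protein(600 + i, spacing = c(6, 6))))
  prof <- build_profile(toy_msa(fam$seq))
  target <- generate_pap_protein(700, spacing = c(6, 6))$seq
  base <- score_sequence(prof, target)$score
  withr::with_seed(12, {
    flank <- paste(sample(c("K", "R", "P", "S", "T"), 40, replace = TRUE),
                   collapse = "")
    expect_gte(score_sequence(prof, paste0(flank, target, flank))$score,
               base - 1e-9)
  })
})

test_that("Gumbel calibration recovers parameters and orders E-values", {
  # parameter recovery on a known Gumbel sample
  withr::with_seed(13, {
    x <- -log(-log(runif(1e4))) / 0.7 + 5
    fit <- fit_gumbel(x)
    expect_equal(fit$lambda, 0.7, tolerance = 0.05)
  })
  expect_error(fit_gumbel(rep(2, 100)), "degenerate")

  fam <- dplyr::bind_rows(lapply(1:6, function(i)
    generate_pap_protein(800 + i, spacing = c(6, 6))))
  prof <- build_profile(toy_msa(fam$seq))
  prof <- calibrate_evalue(prof, n_shuffles = 300, target_lengths = 60,
                           db_size = 220, seed = 14)
  s <- seq(0, 60, by = 5)
  ev <- evalue(prof, s)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev >= 0))
  # E-value at the largest null score is of order db_size / n_shuffles
  null_scores <- withr::with_seed(15, vapply(1:300, function(i) {
    sq <- paste(sample(rownames(prof$log_odds), 60, replace = TRUE),
                collapse = "")
    score_sequence(prof, sq)$score
  }, numeric(1)))
  e_at_max <- evalue(prof, max(null_scores))
  expect_gt(e_at_max, 220 / 300 / 30)
  expect_lt(e_at_max, 220 / 300 * 30)
})

test_that("search recovers family members and excludes random decoys", {
  fam <- generate_divergent_family(5, n_seed = 6, n_core = 20, n_outlier = 0,
                                   core_divergence = 0.2)
  decoys <- dplyr::bind_rows(lapply(1:200, function(i)
    generate_decoy_protein(9000 + i, "random", length = 200)))
  proteome <- tibble::tibble(
    target_id = c(fam$targets$record_id, decoys$record_id),
    seq = c(fam$targets$seq, decoys$seq)
  )
  prof <- build_profile(fam$seed_msa)
  prof <- calibrate_evalue(prof, n_shuffles = 300,
                           target_lengths = nchar(proteome$seq),
                           db_size = nrow(proteome), seed = 2)
  hits <- profile_search(prof, proteome)
  expect_equal(sum(startsWith(hits$target_id, "CORE")), 20)
  expect_lte(sum(startsWith(hits$target_id, "SYNDEC")), 2)
  # sorted by E-value, ties by id
  expect_equal(hits$evalue, sort(hits$evalue))

  # self-recovery: the ungapped seed members are all hits
  expect_equal(
    sort(profile_search(prof, tibble::tibble(
      target_id = fam$seed_msa$id, seq = gsub("-", "", fam$seed_msa$seq)
    ))$target_id),
    sort(fam$seed_msa$id)
  )

  # threshold zero admits nothing
  expect_equal(nrow(profile_search(prof, proteome, evalue_max = 0)), 0)
  # empty proteome: empty result
  expect_equal(nrow(profile_search(prof, proteome[0, ])), 0)
})

test_that("iterative search adds diverged outliers in round 2", {
  fam <- generate_divergent_family(11)
  res2 <- iterative_search(fam$seed_msa, fam$targets, rounds = 2,
                           n_shuffles = 300, seed = 3)
  labelled <- dplyr::left_join(res2, fam$targets,
                               by = c(target_id = "record_id"))
  expect_equal(sum(labelled$tier == "core" & labelled$round == 1), 8)
  expect_equal(sum(labelled$tier == "outlier" & labelled$round == 1), 0)
  expect_equal(sum(labelled$tier == "outlier" & labelled$round == 2), 3)

  # rounds = 1 reproduces the single-round search candidate set
  res1 <- iterative_search(fam$seed_msa, fam$targets, rounds = 1,
                           n_shuffles = 300, seed = 3)
  expect_equal(sort(res1$target_id),
               sort(res2$target_id[res2$round == 1]))
  # round-monotonicity
  expect_true(all(res1$target_id %in% res2$target_id))

  # a round-1-complete family gains nothing in round 2
  fam2 <- generate_divergent_family(21, n_outlier = 0,
                                    core_divergence = 0.2)
  resb <- iterative_search(fam2$seed_msa, fam2$targets, rounds = 2,
                           n_shuffles = 300, seed = 4)
  expect_true(all(resb$round == 1))

  # deterministic given seeds
  expect_identical(res2, iterative_search(fam$seed_msa, fam$targets,
                                          rounds = 2, n_shuffles = 300,
                                          seed = 3))
})

test_that("searching with no round-1 hits warns and returns empty", {
  fam <- generate_divergent_family(31, n_core = 2, n_outlier = 0)
  junk <- dplyr::bind_rows(lapply(1:30, function(i)
    generate_decoy_protein(5000 + i, "random", length = 200)))
  expect_warning(
    res <- iterative_search(fam$seed_msa,
                            tibble::tibble(target_id = junk$record_id,
                                           seq = junk$seq),
                            rounds = 2, n_shuffles = 300, seed = 5),
    "no hits"
  )
  expect_equal(nrow(res), 0)
})
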