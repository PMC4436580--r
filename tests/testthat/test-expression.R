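# Expression summaries and the exact NB differential-accumulation test.

test_that("CPM and log10 transforms follow their definitions", {
  m <- matrix(c(100, 0, 50, 10), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- normalize_cpm(m, c(1e6, 1e6))
  expect_equal(cpm["g1", "s1"], 100)
  expect_equal(cpm["g2", "s1"], 0)
  expect_equal(normalize_cpm(m, c(2e6, 2e6)), cpm / 2)

  lg <- log10_abs(m)
  expect_equal(lg["g2", "s1"], 0)
  expect_equal(log10_abs(matrix(999, 1, 1))[1, 1], 3, tolerance = 1e-3)
  expect_error(log10_abs(matrix(-1, 1, 1)))
})

test_that("per-gene Z-scores standardize rows and honour edge cases", {
  m <- rbind(g1 = c(10, 20, 30), g2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  z <- zscore_by_gene(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))

  withr::with_seed(31, {
    big <- matrix(rpois(600, 50), 60, 10,
                  dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:10)))
    z2 <- zscore_by_gene(big)
    expect_true(all(abs(rowMeans(z2)) < 1e-9))
    expect_true(all(abs(apply(z2, 1, sd) - 1) < 1e-9 |
                      apply(big, 1, sd) == 0))
    # scale/shift invariance
    expect_equal(zscore_by_gene(big * 3 + 7), z2)
  })
  expect_error(zscore_by_gene(matrix(1:3, 3, 1)), "two samples")
})

test_that("common dispersion is recovered by method of moments", {
  simp <- generate_count_matrix(2000, dispersion = 0, seed = 202)
  phi0 <- estimate_common_dispersion(simp$counts, simp$samples$condition,
                                     simp$samples$library_size)
  expect_lt(phi0, 0.02)

  simnb <- generate_count_matrix(2000, dispersion = 0.1, seed = 101)
  phinb <- estimate_common_dispersion(simnb$counts, simnb$samples$condition,
                                      simnb$samples$library_size)
  expect_gt(phinb, 0.05)
  expect_lt(phinb, 0.2)

  # zero-variance input
  const <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10),
                                            paste0("s", 1:4)))
  expect_equal(estimate_common_dispersion(const, rep(c("a", "b"), each = 2),
                                          rep(1e6, 4)), 0)
})

test_that("exact NB test reduces to the binomial split at phi = 0", {
  # most probable outcome: p = 1
  expect_equal(exact_nb_test(c(25, 25), c(25, 25), phi = 0), 1)
  expect_equal(exact_nb_test(c(10, 10), c(10, 10), phi = 0.2), 1)

  # (0, 50) against an even split: two-sided binomial tail by enumeration
  p <- exact_nb_test(0, 50, phi = 0)
  expect_equal(p, brute_binomial_p(0, 50, 1, 1), tolerance = 1e-9)

  withr::with_seed(32, {
    for (i in 1:50) {
      y1 <- rpois(2, 40)
      y2 <- rpois(2, 60)
      p_got <- exact_nb_test(y1, y2, phi = 0)
      p_want <- brute_binomial_p(sum(y1), sum(y2), 2, 2)
      expect_equal(p_got, p_want, tolerance = 1e-9)
    }
  })

  expect_error(exact_nb_test(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("exact NB p-values agree with an established exact test", {
  skip_if_not_installed("edgeR")
  sim <- generate_count_matrix(200, dispersion = 0.1, seed = 303)
  grp <- sim$samples$condition
  dge <- edgeR::DGEList(counts = sim$counts, group = factor(grp,
                                                            c("+P", "-P")))
  dge$samples$norm.factors <- 1
  et <- edgeR::exactTest(dge, dispersion = 0.1)
  mine <- vapply(rownames(sim$counts), function(g) {
    exact_nb_test(sim$counts[g, grp == "+P"], sim$counts[g, grp == "-P"],
                  library_sizes = sim$samples$library_size, phi = 0.1)
  }, numeric(1))
  # same conditioning idea, slightly different pseudo-count handling:
  # demand close agreement, not bit identity
  expect_gt(cor(log10(mine), log10(et$table$PValue), method = "spearman"),
            0.99)
  expect_lt(median(abs(log10(mine) - log10(et$table$PValue))), 0.05)
})

test_that("label swap flips the fold-change and preserves the p-value", {
  sim <- generate_count_matrix(30, dispersion = 0.1, seed = 304,
                               logfc = c(SYNG0002 = 1.5))
  de_a <- test_differential(sim$counts, sim$samples, phi = 0.1)
  flipped <- sim$samples
  flipped$condition <- ifelse(flipped$condition == "+P", "-P", "+P")
  de_b <- test_differential(sim$counts, flipped, phi = 0.1)
  expect_equal(de_a$pvalue, de_b$pvalue, tolerance = 1e-12)
  expect_equal(de_a$log2fc, -de_b$log2fc, tolerance = 1e-12)
})

test_that("family-level Bonferroni correction is applied as stated", {
  res <- tibble::tibble(gene_id = c("a", "b"), tissue = "leaf",
                        log2fc = c(1, 2), pvalue = c(0.001, 0.01))
  out <- call_differential(res, m = 33)
  expect_equal(out$padj, c(0.033, 0.33))
  expect_equal(out$significant, c(TRUE, FALSE))
  # dominance and capping
  expect_true(all(out$padj >= out$pvalue))
  expect_equal(call_differential(tibble::tibble(pvalue = 0.5), m = 33)$padj, 1)
  expect_error(call_differential(res, m = 1), "family size")
})

test_that("null p-values are calibrated and planted effects are recalled", {
  # type-I error and uniformity under the generator's null
  sim <- generate_count_matrix(2000, dispersion = 0.1, seed = 101)
  phi <- estimate_common_dispersion(sim$counts, sim$samples$condition,
                                    sim$samples$library_size)
  de <- test_differential(sim$counts, sim$samples, phi = phi)
  expect_gt(mean(de$pvalue < 0.05), 0.03)
  expect_lt(mean(de$pvalue < 0.05), 0.07)
  ks <- suppressWarnings(stats::ks.test(de$pvalue, "punif"))
  expect_gt(ks$p.value, 0.001)

  # power: planted log2FC = 3 at mu = 200, phi = 0.05, 2 reps, family m = 33
  recalled <- 0
  planted <- 0
  for (s in 1:50) {
    lf <- setNames(rep(3, 5), sprintf("SYNG%04d", 1:5))
    simp <- generate_count_matrix(33, n_reps = 2, dispersion = 0.05,
                                  logfc = lf, baseline_range = c(200, 200),
                                  seed = 7000 + s)
    dep <- test_differential(simp$counts, simp$samples, phi = 0.05, m = 33)
    recalled <- recalled + sum(dep$significant[dep$gene_id %in% names(lf)])
    planted <- planted + length(lf)
  }
  expect_gte(recalled / planted, 0.8)
})

test_that("long-form summary combines counts, log10 and Z-scores", {
  sim <- generate_count_matrix(10, seed = 401)
  summ <- summarize_expression(sim$counts)
  expect_equal(nrow(summ), 10 * 4)
  expect_equal(summ$log10_value, log10(summ$count + 1))
  one <- summ[summ$gene_id == "SYNG0003", ]
  expect_equal(mean(one$zscore), 0, tolerance = 1e-9)
  expect_equal(sd(one$zscore), 1, tolerance = 1e-9)
})
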