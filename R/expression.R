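# Expression summaries and differential transcript accumulation.
#
# Absolute accumulation is summarized as log10(count + 1); relative
# accumulation as per-gene standardized Z-scores. Differential accumulation
# between phosphate regimes is called with an exact conditional
# negative-binomial test (common dispersion, library sizes equalized by
# scaling to the geometric-mean library) and a family-level Bonferroni
# correction.

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot(is.data.frame(counts))
  id_col <- intersect(c("gene_id", "gene", "transcript_id"), names(counts))[1]
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  rownames(m) <- counts[[id_col]]
  m
}

#' Counts-per-million normalization
#'
#' @param counts Gene x sample matrix, or tibble with a gene id column.
#' @param library_sizes Positive per-sample library sizes (same order as
#'   the sample columns).
#' @return Numeric matrix of `count / library_size * 1e6`.
#' @export
normalize_cpm <- function(counts, library_sizes) {
  m <- counts_to_matrix(counts)
  stopifnot(length(library_sizes) == ncol(m), all(library_sizes > 0))
  sweep(m, 2, library_sizes, "/") * 1e6
}

#' log10 absolute expression
#'
#' @param values Non-negative matrix (counts or normalized values).
#' @param pseudocount Added before the log (default 1, so 0 maps to 0).
#' @return `log10(values + pseudocount)`.
#' @export
log10_abs <- function(values, pseudocount = 1) {
  m <- counts_to_matrix(values)
  stopifnot(all(m >= 0))
  log10(m + pseudocount)
}

#' Per-gene standardized Z-scores
#'
#' Each gene's values are centred on the gene mean and divided by the gene
#' standard deviation (sample SD, n - 1 denominator). Genes with zero
#' variance get an all-zero row.
#'
#' @param values Gene x sample matrix (>= 2 samples).
#' @return Matrix of Z-scores; non-constant rows have mean 0 and SD 1.
#' @export
zscore_by_gene <- function(values) {
  m <- counts_to_matrix(values)
  if (ncol(m) < 2) stop("Z-scores require at least two samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Long-form expression summary
#'
#' Convenience wrapper combining [log10_abs()] and [zscore_by_gene()] on
#' raw counts into a tidy table ready for heatmap plotting.
#'
#' @param counts Gene x sample counts (matrix or tibble with `gene_id`).
#' @param pseudocount Pseudocount for the log10 transform.
#' @return Tibble (class `pap_expression`): `gene_id`, `sample`, `count`,
#'   `log10_value`, `zscore`.
#' @export
summarize_expression <- function(counts, pseudocount = 1) {
  m <- counts_to_matrix(counts)
  lg <- log10_abs(m, pseudocount)
  z <- zscore_by_gene(lg)
  out <- tibble(
    gene_id = rep(rownames(m), ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    count = as.vector(m),
    log10_value = as.vector(lg),
    zscore = as.vector(z)
  )
  class(out) <- c("pap_expression", class(out))
  out
}

# Equalize libraries by scaling counts to the geometric-mean library size
# and rounding to pseudo-counts.
equalize_libraries <- function(m, library_sizes) {
  geo <- exp(mean(log(library_sizes)))
  round(sweep(m, 2, library_sizes, "/") * geo)
}

#' Method-of-moments common dispersion
#'
#' For each gene and condition group (>= 2 replicates), computes
#' `max(0, (s^2 - m) / m^2)` on library-size-equalized counts and averages
#' over all gene x group combinations with positive mean. Under a
#' negative-binomial model `Var = mu + phi * mu^2`, this recovers the
#' common dispersion `phi`; Poisson data give values near 0.
#'
#' @param counts Gene x sample counts (matrix or tibble with `gene_id`).
#' @param groups Factor/character of per-sample condition labels.
#' @param library_sizes Per-sample library sizes (default: column sums).
#' @return Non-negative scalar dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       library_sizes = NULL) {
  m <- counts_to_matrix(counts)
  library_sizes <- library_sizes %||% colSums(m)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  eq <- equalize_libraries(m, library_sizes)
  phis <- c()
  for (g in unique(groups)) {
    sub <- eq[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    keep <- mu > 0
    phis <- c(phis, pmax(0, (v[keep] - mu[keep]) / mu[keep]^2))
  }
  if (length(phis) == 0) return(0)
  mean(phis)
}

#' Exact conditional negative-binomial test for one gene
#'
#' Conditions on the total of library-size-equalized pseudo-counts split
#' between the two groups. Under the null, the group totals are
#' negative-binomial with means proportional to group size and dispersions
#' `phi / n_g`; the two-sided p-value sums the probabilities of all splits
#' no more probable than the observed one. With `phi = 0` the conditional
#' law reduces to a binomial split of the total.
#'
#' @param y1,y2 Non-negative integer counts for the two groups.
#' @param library_sizes Per-sample library sizes, ordered as `c(y1, y2)`
#'   (default: all equal).
#' @param phi Common dispersion (>= 0).
#' @return Two-sided p-value in (0, 1].
#' @export
exact_nb_test <- function(y1, y2, library_sizes = NULL, phi = 0) {
  if (any(c(y1, y2) < 0)) stop("counts must be non-negative")
  stopifnot(length(y1) >= 1, length(y2) >= 1, phi >= 0)
  library_sizes <- library_sizes %||% rep(1, length(y1) + length(y2))
  eq <- equalize_libraries(rbind(c(y1, y2)), library_sizes)[1, ]
  s1 <- sum(eq[seq_along(y1)])
  s2 <- sum(eq[-seq_along(y1)])
  total <- s1 + s2
  if (total == 0) return(1)
  n1 <- length(y1)
  n2 <- length(y2)
  mu <- total / (n1 + n2)
  logp_split <- function(a) {
    if (phi > 0) {
      dnbinom(a, mu = n1 * mu, size = n1 / phi, log = TRUE) +
        dnbinom(total - a, mu = n2 * mu, size = n2 / phi, log = TRUE)
    } else {
      dpois(a, n1 * mu, log = TRUE) + dpois(total - a, n2 * mu, log = TRUE)
    }
  }
  lp <- logp_split(0:total)
  obs <- lp[s1 + 1]
  p <- sum(exp(lp[lp <= obs + 1e-10])) / sum(exp(lp))
  min(1, p)
}

#' Differential accumulation calls with family-level Bonferroni correction
#'
#' Runs the exact test for every gene between two condition groups, within
#' each tissue, and applies a Bonferroni correction at the size of the
#' tested family: `padj = min(1, p * m)`. Log2 fold-changes (second
#' condition over first, e.g. -P over +P) are computed from equalized group
#' means with a pseudocount of 0.5.
#'
#' @param counts Gene x sample counts (matrix or tibble with `gene_id`).
#' @param samples Tibble describing the columns of `counts`, in order:
#'   `sample`, `condition` (two levels; the first level is the reference),
#'   optional `tissue`, optional `library_size`.
#' @param phi Common dispersion; `NULL` (default) estimates it per tissue
#'   with [estimate_common_dispersion()].
#' @param m Bonferroni family size (default: number of genes tested;
#'   must be at least that).
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble (class `pap_de`): `gene_id`, `tissue`, `log2fc`,
#'   `pvalue`, `padj`, `significant`, plus `phi` used.
#' @export
#' @examples
#' sim <- generate_count_matrix(n_genes = 20, seed = 1,
#'                              logfc = c(SYNG0001 = 3))
#' de <- test_differential(sim$counts, sim$samples, phi = 0.1)
#' dplyr::filter(de, significant)
test_differential <- function(counts, samples, phi = NULL, m = NULL,
                              alpha = 0.05) {
  mat <- counts_to_matrix(counts)
  stopifnot(nrow(samples) == ncol(mat))
  cond <- as.factor(samples$condition)
  stopifnot(nlevels(cond) == 2)
  tissues <- samples$tissue %||% rep("all", nrow(samples))
  lib <- samples$library_size %||% colSums(mat)
  m_family <- m %||% nrow(mat)
  if (m_family < nrow(mat)) {
    stop("Bonferroni family size m must be >= the number of tested genes")
  }
  out <- purrr::map(unique(tissues), function(tis) {
    sel <- tissues == tis
    sub <- mat[, sel, drop = FALSE]
    c_t <- cond[sel]
    lib_t <- lib[sel]
    phi_t <- phi %||% estimate_common_dispersion(sub, c_t, lib_t)
    i1 <- which(c_t == levels(cond)[1])
    i2 <- which(c_t == levels(cond)[2])
    eq <- equalize_libraries(sub, lib_t)
    res <- purrr::map(rownames(sub), function(g) {
      p <- exact_nb_test(sub[g, i1], sub[g, i2], lib_t, phi_t)
      lfc <- log2((mean(eq[g, i2]) + 0.5) / (mean(eq[g, i1]) + 0.5))
      tibble(gene_id = g, tissue = tis, log2fc = lfc, pvalue = p,
             phi = phi_t)
    }) |> dplyr::bind_rows()
    res
  }) |> dplyr::bind_rows()
  call_differential(out, m = m_family, alpha = alpha)
}

#' Apply the family-level Bonferroni correction to exact-test results
#'
#' @param results Tibble with at least `pvalue` (and optionally `log2fc`).
#' @param m Family size; must be >= the number of tested transcripts per
#'   tissue.
#' @param alpha Significance level.
#' @return `results` with `padj = min(1, pvalue * m)` and `significant`
#'   columns, classed `pap_de`.
#' @export
call_differential <- function(results, m, alpha = 0.05) {
  n_per <- if ("tissue" %in% names(results)) {
    max(table(results$tissue))
  } else {
    nrow(results)
  }
  if (m < n_per) stop("Bonferroni family size m must be >= tests per tissue")
  out <- results |>
    dplyr::mutate(
      padj = pmin(1, .data$pvalue * m),
      significant = .data$padj < alpha
    )
  class(out) <- unique(c("pap_de", class(out)))
  out
}

#' @export
glance.pap_de <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    n_tissues = length(unique(x$tissue %||% "all")),
    phi = mean(x$phi %||% NA_real_)
  )
}
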