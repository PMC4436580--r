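# Seeded negative-binomial count-matrix generator.

#' Generate a negative-binomial count matrix with planted fold-changes
#'
#' Counts for gene g in sample s are drawn from a negative binomial with
#' mean `library_size_s * q_g * FC_g^[s is treated]` and common dispersion
#' `phi` (`phi = 0` gives Poisson marginals). Baseline relative abundances
#' `q_g` are drawn log-uniformly so that a sample at the geometric-mean
#' library has mean counts in `baseline_range`. The design has two
#' conditions with `n_reps` replicates each (the mining study used two
#' biological replicates per phosphate regime).
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per condition (>= 2).
#' @param library_sizes Per-sample library sizes (default 1e6 for all
#'   `2 * n_reps` samples).
#' @param dispersion Common NB dispersion `phi >= 0`.
#' @param logfc Named numeric vector `gene_id -> log2 fold-change` planted
#'   in the treated condition; genes without an entry are null. Gene ids
#'   are `SYNG0001 ...`.
#' @param baseline_range Range of mean counts (at the geometric-mean
#'   library) for the log-uniform baseline draw.
#' @param tissue Tissue label stored in the sample sheet.
#' @param seed Integer seed; deterministic output.
#' @return List: `counts` (matrix genes x samples), `samples` (tibble
#'   `sample`, `tissue`, `condition` in `+P`/`-P`, `replicate`,
#'   `library_size`), `truth` (tibble `gene_id`, `baseline`, `logfc`).
#' @export
#' @examples
#' sim <- generate_count_matrix(n_genes = 5, seed = 1)
#' sim$counts
generate_count_matrix <- function(n_genes, n_reps = 2, library_sizes = NULL,
                                  dispersion = 0.1, logfc = c(),
                                  baseline_range = c(100, 1000),
                                  tissue = "leaf", seed = 1) {
  stopifnot(n_reps >= 2, dispersion >= 0)
  n_samples <- 2 * n_reps
  library_sizes <- library_sizes %||% rep(1e6, n_samples)
  stopifnot(length(library_sizes) == n_samples, all(library_sizes > 0))
  gene_ids <- sprintf("SYNG%04d", seq_len(n_genes))
  unknown <- setdiff(names(logfc), gene_ids)
  if (length(unknown) > 0) {
    stop("logfc names not in gene set: ", paste(unknown, collapse = ", "))
  }
  geo <- exp(mean(log(library_sizes)))
  condition <- rep(c("+P", "-P"), each = n_reps)
  with_seed(seed, {
    baseline <- exp(runif(n_genes, log(baseline_range[1]),
                          log(baseline_range[2])))
    lfc <- setNames(rep(0, n_genes), gene_ids)
    lfc[names(logfc)] <- logfc
    q <- baseline / geo
    mu <- outer(q, library_sizes) *
      2^outer(lfc, as.numeric(condition == "-P"))
    counts <- matrix(
      if (dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      } else {
        rpois(length(mu), mu)
      },
      nrow = n_genes,
      dimnames = list(gene_ids, sprintf("%s_%s_rep%d", tissue, condition,
                                        rep(seq_len(n_reps), 2)))
    )
    list(
      counts = counts,
      samples = tibble(
        sample = colnames(counts),
        tissue = tissue,
        condition = condition,
        replicate = rep(seq_len(n_reps), 2),
        library_size = library_sizes
      ),
      truth = tibble(gene_id = gene_ids, baseline = baseline,
                     logfc = unname(lfc))
    )
  })
}
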