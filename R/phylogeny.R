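# Distance-based phylogeny: p-distances, neighbor joining, bootstrap
# support, and reference-guided group assignment. Family groups (I, II,
# III) and subgroups (e.g. Ia-2) are assigned to query sequences from the
# smallest clade containing all reference members of a label.

#' Pairwise p-distance matrix from an alignment
#'
#' `d(i, j)` is the fraction of mismatching residues over columns where
#' neither sequence has a gap (pairwise deletion). Errors if any pair has
#' no comparable column.
#'
#' @param msa Alignment tibble (`id`, `seq`), as from [read_msa()] or
#'   [generate_alignment_on_tree()].
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pdistance <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard agglomerative neighbor joining on a distance matrix; on
#' additive distances the generating tree is recovered exactly. Negative
#' branch-length estimates are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with taxa dimnames.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining requires at least 3 taxa")
  stopifnot(isSymmetric(unname(d)), all(is.finite(d)), all(diag(d) == 0))
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative branch-length estimates clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal bipartition of the full-data
#' tree with the fraction of replicates containing it (in [0, 1], stored
#' in `node.label`).
#'
#' @param msa Alignment tibble.
#' @param n_replicates Bootstrap replicates (>= 1; classic analyses use
#'   1000).
#' @param seed Integer seed.
#' @return `phylo` tree with numeric `node.label` supports (the root node
#'   carries `NA`).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1) {
  stopifnot(n_replicates >= 1)
  m <- msa_matrix(msa)
  full <- nj_tree(pdistance(msa))
  boots <- with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(i) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      suppressWarnings(nj_tree(pdistance(matrix_msa(
        m[, cols, drop = FALSE]
      ))))
    })
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_replicates
  support[1] <- NA  # root of the unrooted representation, not a bipartition
  full$node.label <- support
  full
}

#' Assign family groups from reference leaves
#'
#' The tree is midpoint-rooted; for each label, the smallest clade
#' containing all reference leaves of that label is found, and every
#' non-reference leaf inside exactly one label's clade receives that label
#' (nested clades resolve to the most specific, i.e. smallest). Leaves in
#' no clade, or in tied overlapping clades, are `unplaced`. Reference
#' leaves always map to their own label.
#'
#' @param tree A `phylo` tree whose tips include all reference ids.
#' @param reference_labels Named character vector `ref_id -> label`, or a
#'   tibble with columns `ref_id`, `label`.
#' @return Tibble: `member_id`, `group`, `is_reference`.
#' @export
assign_groups <- function(tree, reference_labels) {
  if (is.data.frame(reference_labels)) {
    reference_labels <- setNames(reference_labels$label,
                                 reference_labels$ref_id)
  }
  refs <- names(reference_labels)
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing) > 0) {
    stop("reference id(s) not in tree: ", paste(missing, collapse = ", "))
  }
  rooted <- phangorn::midpoint(tree)
  labels <- unique(unname(reference_labels))
  clade_tips <- lapply(labels, function(lab) {
    members <- refs[reference_labels == lab]
    if (length(members) == 1) return(members)
    node <- ape::getMRCA(rooted, members)
    ape::extract.clade(rooted, node)$tip.label
  })
  names(clade_tips) <- labels
  assignment <- vapply(tree$tip.label, function(tip) {
    if (tip %in% refs) return(unname(reference_labels[tip]))
    containing <- labels[vapply(clade_tips, function(tips) tip %in% tips,
                                logical(1))]
    if (length(containing) == 0) return("unplaced")
    sizes <- vapply(clade_tips[containing], length, 1L)
    smallest <- containing[sizes == min(sizes)]
    if (length(smallest) > 1) return("unplaced")
    smallest
  }, character(1))
  tibble(member_id = tree$tip.label, group = unname(assignment),
         is_reference = tree$tip.label %in% refs)
}
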