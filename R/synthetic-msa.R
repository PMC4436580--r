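# Seeded simulation of protein alignments on a known tree.

#' Evolve a protein alignment on a tree
#'
#' Simulates site-independent sequence evolution along a tree under a
#' uniform-rate replacement process (Jukes-Cantor-type model over the 20
#' amino acids, via `phangorn::simSeq`): with branch lengths in expected
#' substitutions per site, every site evolves independently and all
#' replacements are equally likely. No indels are simulated, so leaf
#' sequences come back gap-free and aligned.
#'
#' @param tree A `phylo` tree (>= 3 leaves, non-negative branch lengths)
#'   or a Newick string.
#' @param length Number of alignment columns.
#' @param rate Overall rate multiplier.
#' @param seed Integer seed.
#' @return Alignment tibble (`id`, `seq`) with one row per leaf.
#' @export
#' @examples
#' msa <- generate_alignment_on_tree("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);",
#'                                   length = 100, seed = 1)
generate_alignment_on_tree <- function(tree, length, rate = 1, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3,
            all(tree$edge.length >= 0), length >= 1)
  sim <- with_seed(seed, {
    phangorn::simSeq(tree, l = length, type = "AA", rate = rate)
  })
  m <- toupper(as.character(sim))
  tibble(id = rownames(m), seq = apply(m, 1, paste, collapse = ""))
}
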