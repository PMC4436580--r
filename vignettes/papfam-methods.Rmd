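---
title: "Methods: models, parameters and design decisions in papfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design decisions in papfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papfam)
```

`papfam` packages the standard workflow for mining and characterizing a
plant purple acid phosphatase (PAP) gene family: profile-based candidate
retrieval from a predicted proteome, curation by the five conserved
metal-binding residue blocks, scanning of upstream regions for the PHR1
binding site (P1BS), expression and differential-accumulation analysis
between phosphate regimes, distance-based phylogeny with group
assignment, and co-localization with QTL intervals. This vignette
documents the underlying models, the tunable parameters and their
defaults, the synthetic-data generators the test suite is built on, and
the decisions taken where the workflow leaves genuine freedom.

## Profile search

The retrieval engine is a position-specific scoring model (PSSM), not a
full profile HMM. From a seed family alignment, columns with a gap
fraction above `gap_fraction_max` (default 0.5) become insert-only;
retained columns get per-residue log-odds scores in bits,

$$ s_c(a) = \log_2 \frac{(n_c(a) + \tau\,b_a)\,/\,(N_c + \tau)}{b_a}, $$

with background $b$ uniform over the 20 amino acids and a
background-proportional pseudocount mass $\tau$ (default 1.0). Targets
are scored by affine-gap local dynamic programming (gap open −11 bits,
gap extend −1 bit — conventional profile-alignment penalties, all
configurable), implemented in C++ with full traceback. Local alignment
means the score is never negative and is insensitive to unrelated
flanking sequence. Unknown residues (X, B, Z, U) score 0 bits at every
column: neutral with respect to the background.

Statistical significance follows the extreme-value behavior of optimal
local alignment scores. `calibrate_evalue()` scores `n_shuffles`
(default 500, minimum 200) random background sequences at the *mean*
target length, fits a Gumbel location/scale $(\mu, \beta)$ by maximum
likelihood (Nelder–Mead on the negative log-likelihood, moment-based
start), and converts scores with
$E(s) = K \cdot N \cdot e^{-\lambda s}$, $\lambda = 1/\beta$,
$K = e^{\lambda\mu}$, for a database of $N$ sequences. Calibrating at
the mean target length and skipping per-sequence length correction is a
deliberate simplification: the candidate decision happens far in the
tail, where the length effect is second-order for proteome-scale
screens. The inclusion threshold is `E < 0.01`.

`iterative_search()` mirrors the classic two-round strategy: round 2
rebuilds the profile from the seed alignment *plus* the round-1 hit
regions, stacked column-wise by each hit's dynamic-programming trace (no
realignment step, so no alignment program is needed), recalibrates and
searches again. Reported candidates are the union across rounds labeled
with the first round of discovery, which makes the candidate set
monotone in the number of rounds by construction. Hits are ordered by
E-value with lexicographic ties on the target id, so results are
deterministic given the calibration seed.

What this is not: a forward-algorithm profile HMM. Bit scores and hit
lists from HMM-based tools are not reproduced; the package's own tests
validate the scorer against exhaustive alignment enumeration on small
instances and against planted-truth retrieval instead.

## Conserved-block validation

Family membership requires the five degenerate blocks
`GDXG, GDXXY, GNH(D/E), VXXH, GHXH` (lengths 4, 5, 4, 4, 4) in
canonical order. A first-block variant `DXG` is also in circulation for
this family; both ship as named presets (`"gdxg"`, the default, and
`"dxg"`) and the choice is never made silently. A candidate is `valid`
when one occurrence per block can be selected with strictly increasing
starts and non-overlapping spans. Non-overlap is our reading of
"canonical order" — the blocks are distinct metal-coordinating sites, so
two blocks sharing residues would be biologically incoherent.
Inter-block spacing is deliberately unconstrained: spacing in real
family members is variable and no bound is defensible. The ordered
selection is found greedily (earliest feasible occurrence per block),
which is optimal here because all occurrences of a block share one
length; the test suite checks it against exhaustive enumeration of all
occurrence tuples.

Genes are judged on their best splice model: any transcript with all
five blocks validates the gene (ties prefer the primary transcript, then
the smallest id), mirroring the rescue of genes whose primary model
lacks blocks that a secondary model encodes. Removal reasons are exactly
the two failure classes, `missing_blocks` and `non_canonical` — the
manual "inspection" step of family curation is thereby fully automated,
since both documented removal classes map 1:1 onto the statuses.

## P1BS scanning

The P1BS element `GNATATNC` is parsed as an IUPAC motif (16 of the
65 536 8-mers match). Scanning checks both strands, but the consensus
equals its own reverse complement, so a site matching on the minus
strand always matches on the plus strand at the same position; each
location is reported once with strand `+`. A physical binding site
exists once, and per-gene counts follow that convention. Offsets are
the match's 5′-most base as a negative 1-based distance (−1 = base
immediately before the anchor).

Two anchors are supported, because the two conventions in circulation
genuinely disagree: upstream windows can be taken from the
*translational* start (ATG) or the *transcriptional* start. The default
is the translational start — the packaged per-gene reference table for
the maize family states its locations relative to the predicted
translational start — but `extract_upstream()` takes either, and the
choice is recorded in the output. Ambiguous `N` bases in genomic
sequence match nothing, not even the motif's N positions; a phantom
site in an assembly gap is worse than a missed one.

The packaged reference table (33 genes, counts, locations,
localization classes) is validated on load: row count, count/location
consistency and the window bound must hold exactly. Summaries are
always recomputed from the table: with the default 1000-bp proximal
window, it yields 19 genes with any site and 14 with a proximal site.

## Expression and differential accumulation

Absolute accumulation is `log10(count + 1)`; relative accumulation is
the per-gene Z-score (sample SD, $n-1$), computed here on the log10
scale. Zero-variance genes get an all-zero Z row rather than `NaN` —
heatmap-friendly and honest about "no signal". `summarize_expression()`
returns both in long form.

The differential test is an exact conditional negative-binomial test.
Libraries are equalized by scaling counts to the geometric-mean library
size and rounding; the common dispersion is estimated by the method of
moments, averaging $\max(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2)$ over
gene-by-condition groups with at least two replicates. The per-gene
truncation at 0 biases the average upward when counts are small, so the
estimator is intended for the moderately-to-well-expressed regime; the
generator's default baseline range (means 100–1000 at the
geometric-mean library, log-uniform) reflects the family-level count
depths this analysis targets, and in that regime Poisson data give
estimates below 0.02 and a true dispersion of 0.1 is recovered well
within a factor of two.

For the test itself, group totals of equalized counts are conditioned
on their sum: under the null the two totals are NB with means
proportional to group size and dispersion $\phi/n_g$, and the two-sided
p-value sums all splits no more probable than the observed one
(probabilities compared with a small log-scale tolerance so exact ties
count). At $\phi = 0$ the conditional law is exactly the binomial
split, which the test suite exploits as an enumeration oracle; an
established exact-test implementation agrees to high precision on
simulated data. Multiplicity is handled the way family-focused studies
do: Bonferroni at the size of the family tested within a tissue,
`padj = min(1, p · m)`, significance at `padj < 0.05`. Fold-changes are
log2 of equalized group means with a 0.5 pseudocount, so zero counts
stay finite. Transcript-level input ids are accepted as-is; swapping a
gene's quantified transcript (as family studies occasionally do when
only a secondary model responds) is a deliberate manual step, not
automated.

## Phylogeny

Trees are built by neighbor joining on p-distances
(mismatches / compared columns, pairwise deletion of gapped columns).
This is a deliberate, documented substitution of a likelihood method:
the consumed output of the tree step is *group membership*, not branch
lengths, and NJ admits exact small-instance oracles (it provably
recovers the generating tree from additive distances, which the tests
check exhaustively up to 8 taxa). Published topologies and bootstrap
percentages from likelihood software are therefore not reproduction
targets. Negative NJ branch estimates are clamped to zero with a
warning. Bootstrap supports are the fraction of column-resampled
replicates containing each internal bipartition of the full-data tree.

Group and subgroup labels (I, II, III, Ia-2, ...) propagate from
reference leaves: the tree is midpoint-rooted (displayed family trees
are rooted without a stated rooting, and midpoint is the assumption-free
choice), each label's clade is the smallest one containing all its
references, and a query leaf takes the most specific (smallest)
containing clade's label. Queries in no clade — or in tied,
non-nested clades — are `unplaced` rather than guessed.

## Genome map

Intervals are 0-based half-open internally (BED semantics; 1-based only
at I/O boundaries that demand it). `colocalize()` classifies gene ×
feature pairs as `within`, `overlaps`, or `proximal`; "close to" a QTL
is quantified by a slop parameter defaulting to 1 Mb, a deliberately
generous figure for consensus QTL intervals on a maize-scale physical
map, and configurable because no published definition exists.
Adjacent-but-disjoint intervals count as proximal with gap 0, never as
overlapping.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded (one master seed per call, deterministically
split across records) and returns an exact truth table.

- **Proteins**: block instantiations separated by uniform-length random
  filler, rejection-sampled so the realized block occurrences are
  *exactly* the planted ones — truth labels are certain, not
  probabilistic. Decoys mirror the two curation-failure classes
  (exactly four blocks; all five with two adjacent blocks swapped) plus
  i.i.d.-residue negatives. The default curation-set sizes (33 true +
  11 missing-block + 2 scrambled = 46) mirror the maize family's
  published curation arithmetic.
- **Two-tier families** (`generate_divergent_family()`): a seed family,
  a core tier at ~0.45 per-site divergence from the seed centroid and
  an outlier tier ~0.45 further along the same lineage. These defaults
  were chosen so that a seed-built profile retrieves the core but not
  the outliers, which only a hit-enriched round-2 profile reaches —
  i.e. the construction realizes the two-round discovery pattern it
  exists to exercise.
- **Upstream DNA**: uniform ACGT with motif words planted at stated
  offsets/strands; spurious matches anywhere (either strand) are
  destroyed by resampling single bases outside planted spans, giving
  100% sensitivity / 0 false-positive ground truth. Overlapping plants
  are rejected as ambiguous truth.
- **Counts**: NB draws with mean
  `library_size × q_g × FC^[treated]` and common dispersion; two
  conditions, default two replicates each, matching the two-biological-
  replicate design typical of these experiments.
- **Alignments**: evolved on a known tree under uniform-rate
  replacement over the 20 amino acids (Jukes–Cantor-type, via
  `phangorn::simSeq`); no indels.

What passing tests on these inputs *do not* show: real proteomes have
compositional bias, real promoters are not uniform ACGT, real counts
have gene-wise dispersion and real alignments have indels and
rate-heterogeneous sites. The generators validate the machinery —
coordinate conventions, truth recovery, statistical calibration — not
the biology of any particular genome.

## Problem sizes and numerical choices

The test suite runs at desk scale by choice: oracle equivalences use
exhaustive enumeration where it is exact (profiles ≤ 3 columns,
sequences ≤ 4 residues; all occurrence tuples; all-pairs interval
comparison; binomial enumeration), statistical calibration uses 2000
simulated null genes and 50 power-simulation seeds, and phylogeny
checks use 10^4-column simulated alignments with 100 bootstrap
replicates. Gumbel calibration in tests uses 300 null sequences.

Numerical conventions worth knowing: probability ties in the exact test
are compared with a `1e-10` log-scale tolerance; Z-scores of
zero-variance genes are 0; E-values use the fitted tail approximation
(not the full Gumbel CDF), which is the regime where decisions happen;
all tie-breaks (hit ordering, transcript choice, Q-matrix joins) resolve
lexicographically or by the established implementation's deterministic
rule, so every pipeline stage is reproducible bit-for-bit given its
seeds.

## Known limitations

- The PSSM + Gumbel scorer is a stand-in for profile-HMM inference;
  deeply diverged members recoverable by forward-algorithm scoring may
  be missed, and two rounds partially (not fully) compensate.
- The common-dispersion moment estimator is biased upward for weakly
  expressed genes; tagwise dispersion is out of scope.
- The NB test equalizes libraries by simple scaling; quantile-based
  equalization would be preferable for strongly unequal libraries.
- Group assignment depends on midpoint rooting; a misplaced root on
  very asymmetric trees could merge clades.
- No TMM normalization, no read mapping, no alignment construction:
  alignments and counts are consumed as inputs.
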