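# papfam

Genome-wide identification and characterization of plant **purple acid
phosphatase (PAP)** gene families, built around the maize (*Zea mays*)
family as the model case.

PAPs are metallophosphoesterases that liberate inorganic phosphate from
organic phosphoesters and are central to the plant phosphate-starvation
response. Family membership is defined by five short conserved
metal-binding residue blocks in fixed N-to-C order —
`GDXG, GDXXY, GNH(D/E), VXXH, GHXH` — and the promoters of
phosphate-responsive family members carry the PHR1 binding site (P1BS),
the imperfect palindrome `GNATATNC`. `papfam` implements the full
identification-and-characterization workflow as composable, tested
tibble-in/tibble-out functions:

- **Profile search** — a position-specific scoring model (log-odds in
  bits, background-proportional pseudocounts) built from a seed family
  alignment, scored against target proteomes by affine-gap local dynamic
  programming (Rcpp). E-values come from a Gumbel law fitted by maximum
  likelihood to scores of random background sequences:
  `E(s) = K · N · exp(−λs)`. Candidates pass at `E < 0.01`, optionally in
  two rounds (`iterative_search()`), where round 2 rebuilds the profile
  from round-1 hit regions to reach diverged family members.
- **Conserved-block validation** — `validate_blocks()` classifies each
  candidate as `valid` (all five blocks selectable in canonical,
  non-overlapping order), `missing_blocks`, or `non_canonical`;
  `select_best_transcript()` rescues genes whose secondary splice model
  encodes all five blocks; `filter_candidates()` applies the curation
  filter gene-wise.
- **P1BS scanning** — IUPAC motif matching on both strands of upstream
  windows (default 2500 bp), with palindromic double-counts suppressed and
  signed offsets relative to the gene anchor (`scan_p1bs()`,
  `tabulate_p1bs()`, `summarize_p1bs()`). The published per-gene survey
  for the 33 maize genes ships as a validated fixture
  (`read_p1bs_reference()`).
- **Expression** — log10 absolute accumulation, per-gene Z-scores, and
  differential accumulation between phosphate regimes (+P / −P) by an
  exact conditional negative-binomial test with method-of-moments common
  dispersion and a family-level Bonferroni correction
  (`test_differential()`).
- **Phylogeny** — p-distance + neighbor-joining trees with column-resample
  bootstrap supports (`bootstrap_support()`) and reference-guided
  group/subgroup assignment by smallest containing clade
  (`assign_groups()`).
- **Genome map** — co-localization of gene loci with QTL and isozyme
  intervals (`colocalize()`), with `within` / `overlaps` / `proximal`
  calls.
- **Synthetic data** — seeded generators for every input class (proteins
  with planted blocks, decoys, upstream DNA with planted motifs,
  negative-binomial count matrices, alignments evolved on known trees), so
  the entire pipeline is testable against exact ground truth with no
  downloads.

## Worked example

The curation arithmetic on a generated candidate set — 33 family-true
proteins, 11 missing-block decoys, 2 scrambled-order decoys:

```r
library(papfam)

candidates <- generate_candidate_set(seed = 1)   # 46 candidates
report <- filter_candidates(candidates)
dplyr::count(report, kept, reason)
#> # A tibble: 3 × 3
#>   kept  reason             n
#>   <lgl> <chr>          <int>
#> 1 FALSE missing_blocks    11
#> 2 FALSE non_canonical      2
#> 3 TRUE  <NA>              33
```

The filter keeps exactly the 33 block-valid genes and removes the 13
decoys, each with the reason class it was planted with.

Scanning an upstream region with two planted P1BS sites recovers them at
their signed offsets (5′-most base, relative to the translational start):

```r
up <- generate_upstream_set(planted = list(ZmPap10 = c(-232, -2463)), seed = 1)
tabulate_p1bs(scan_p1bs(up$sequences), up$sequences$gene_id)
#> # A tibble: 1 × 4
#>   gene_id p1bs_count locations location_str
#>   <chr>        <int> <list>    <chr>
#> 1 ZmPap10          2 <int [2]> -232, -2463
```

The packaged reference survey of the 33-member maize family:

```r
summarize_p1bs(read_p1bs_reference())
#> # A tibble: 1 × 3
#>   n_genes n_with_any n_with_proximal
#>     <int>      <int>           <int>
#> 1      33         19              14
```

19 of the 33 genes carry at least one P1BS within 2500 bp of the
translational start; 14 have a site within 1000 bp.

Result types plot directly: `autoplot()` methods cover expression
summaries (heatmaps), differential calls, P1BS maps and profile
information content, and `tidy()`/`glance()` expose fitted profile and
E-value models as tibbles.

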