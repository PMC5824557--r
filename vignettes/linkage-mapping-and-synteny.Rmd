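---
title: "Full-sib linkage maps, consensus merging and synteny mapping with sibmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-sib linkage maps, consensus merging and synteny mapping with sibmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibmap)
```

# The problem

Non-model species rarely have an assembled genome, but a dense genetic
linkage map built from a few full-sib families of SNP genotypes can stand
in for one: it orders markers along chromosomes (linkage groups), gives
them additive centiMorgan positions, and — through sequence similarity of
the marker loci to assembled genomes of related species — supports
comparative analyses such as locating candidate genes and QTL markers on
the map. `sibmap` implements this entire chain for the outbred
full-sib ("CP") design, together with a ground-truth simulator that makes
every stage testable without external data.

# The data model

Each marker locus in a full-sib cross falls into one of five segregation
types depending on the parental genotypes: `ABxCD` (both parents
heterozygous, four alleles), `EFxEG` (three alleles), `HKxHK` (same two
alleles in both parents, 1:2:1 offspring ratio), and the one-parent
testcross configurations `LMxLL` and `NNxNP` (1:1). Only a parent that is
heterozygous at *both* loci of a pair contributes meioses to that pair's
linkage signal; mixed informativeness is the central complication of the
design and drives most of the algorithmic choices below.

# Marker quality control

`filter_markers()` applies, in order: removal of offspring with more than
50% missing calls; removal of loci with call rate below 90%; a
within-family minor-allele-frequency filter at 0.05 (computed over
parental plus offspring alleles, because family data carry no population
frequencies); and a Pearson chi-square test of segregation distortion
against the type's Mendelian ratio at the 5% level with Bonferroni
correction over the loci actually tested in the current build. `HKxHK`
loci are tested on their three genotype classes (1:2:1) rather than on
allele counts, which is the standard choice when the heterozygote class is
observable.

`bin_cosegregating()` groups loci whose call vectors are identical,
including the positions of missing data — a conservative rule: two loci
that differ only where one is missing *might* co-segregate, but their
identity is untestable there, so they are kept apart. One representative
per bin is mapped; the passengers are re-attached afterwards at the
representative's position.

# Two-point estimation

`estimate_two_point()` performs simultaneous maximum-likelihood estimation
of the recombination fraction and the parental linkage phases. For each
admissible phase configuration (coupling/repulsion per informative
parent), the likelihood sums over the parental transmissions compatible
with each observed genotype pair — for example the `h/k` class of an
`HKxHK` marker does not reveal which parent transmitted `h` — and rf is
maximized by EM over these latent transmissions. The reported estimate is
the phase with the highest likelihood; ties break toward coupling. The LOD
score is the log10 likelihood ratio against rf = 1/2. Numerical settings:
EM initialized at rf = 0.25, convergence at 1e-6 on the log-likelihood,
at most 100 iterations, rf clamped to [0, 0.5]. Pairs whose two phases are
within 0.1 LOD of each other are flagged (`phase_gap_lod`) and never used
to seed an ordering, because their rf is conditional on an essentially
arbitrary phase choice.

A parent outside the estimation scope (for sex-specific maps) or not
heterozygous at both loci enters the likelihood with free recombination,
which makes single-parent estimation exact rather than approximate.

# Grouping, ordering and cleaning

Loci join the same linkage group when connected by pairs with LOD >= 6 and
rf <= 0.35 (transitive closure via graph components; thresholds
configurable). Within a group, a seed order is grown by greedy insertion
starting from the most informative loci — those heterozygous in both
parents, whose pairs have twice the meioses and can bridge the maternal
and paternal information — and the remaining loci are inserted at their
best position. The order is then polished by alternating two local
searches until neither improves: a ripple that permutes every sliding
window of 4 loci, and a relocation sweep that re-inserts each locus at its
optimal position (displacements larger than the ripple window cannot be
repaired by the ripple alone). Candidate orders are compared strictly
lexicographically on (fewest expected crossovers, highest likelihood,
shortest map). The crossover term is the sum of adjacent recombination
fractions — the per-meiosis scale — rather than rf times the number of
informative meioses: the latter double-weights dual-parent pairs and, in
groups of mixed informativeness, systematically steers the path through
chains of one-parent loci, which we found scrambles orders badly. The
likelihood term is the sum of adjacent LODs and the length term the sum of
adjacent mapping-function distances. Orientation is fixed by placing the
smaller terminal locus id first.

Cleaning (`clean_order()`) mirrors standard map QC: offspring whose total
crossover count exceeds mean + 3 SD are removed; an isolated call that
disagrees with identical flanking founder strands within a 5 cM window (a
"tight double crossover", the signature of a genotyping error) is set to
missing; terminal loci hanging more than 20 cM off the group, and interior
loci far from both neighbours that are themselves close, are dropped. The
group is then re-estimated and re-ordered, and the cycle repeats up to
three times — iteration matters because each round of masking moves the
provisional positions and exposes further isolated flips. A caveat that
the simulator makes visible: under a no-interference crossover model some
tight double crossovers are genuine, so on *error-free* simulated data the
cleaning removes real recombination and shortens maps by roughly 10–20%.
Real meiosis exhibits strong positive interference at these scales, and at
the realistic default error rate (0.5%) the removal of error-induced
recombination dominates and lengths come out close to truth.

Final positions default to a windowed weighted least squares
(`wls_positions()`): every estimable pair within six order positions
contributes its mapping-function distance as an observation on the
intervening gaps, weighted by LOD, and the gaps are solved jointly
(negative solutions clipped to zero). Accumulating only adjacent-pair
distances (`compute_positions()`, also exported, and used for the
provisional positions during cleaning) propagates every local estimation
error into the total; distances spanning several intervals constrain the
sum and, across our simulations, reduce worst-case length error from
about +45% to under 15%. Kosambi is the default mapping function (Haldane
available), matching the convention of the mapping-software lineage this
design follows.

# Consensus merging

With two family maps, `detect_conflicts()` matches linkage groups by
maximal shared-locus overlap (a tie is an error, not a guess) and flags
every shared locus pair ordered oppositely. Conflicted loci invariably sit
in zero-recombination clusters — co-positioned loci whose internal order
the family provides no information about. `resolve_conflicts()` therefore
removes each conflicted locus from the map in which it is clustered; if
clustered in both, from the map with the larger cluster (tie: map B,
logged); up to three rounds, with conflicts re-detected between rounds.
Because the module operates on position tables, "re-ordering" between
rounds leaves surviving positions unchanged; the genotype-level re-run the
original protocol performed cannot change the relative order of the
surviving loci it had already mapped, so this is a faithful
simplification. Conflicts surviving the final round are reported, never
dropped. Note a structural property: a conflicted locus is by definition
shared, so removing it from one family map always leaves it in the other —
no locus is ever lost from the final consensus.

`merge_maps()` merges each matched linkage-group pair by linear
programming: consensus positions for the union of loci minimize the mean
absolute difference to the component maps (standard absolute-value
linearization), subject to every component's order — at least
epsilon = 0.01 cM between strictly ordered loci (below map resolution, but
preventing degenerate collapse) and equality for co-positioned ones unless
the other map strictly orders them. The LP is solved per linkage group
with `boot::simplex()`; achieved MAE is reported overall, per LG and per
component map.

# Synteny

`assign_anchors()` reduces a similarity-hit table to at most one genome
anchor per locus: best bitscore, e-value at most 1e-10, and a 10% bitscore
margin over the best hit on any other chromosome — loci with ambiguous
placement stay unanchored. These thresholds are this package's choices
(config-exposed), made to enforce unique anchoring. `find_blocks()` scans
each linkage group's anchored loci in cM order and emits maximal runs on
one chromosome with monotone bp in either direction (inversions appear as
minus-orientation blocks), split wherever a locus anchored elsewhere
interrupts. An order mismatch closer than 5% of the linkage-group length
to its offending neighbour is attributed to local rearrangement or
ordering noise: the locus stays in the block but is ignored for direction.
A single anchored locus is not a block (minimum two members, consistent
with the ~3 loci/block scale of typical comparisons). `block_stats()`
reports counts, averages, Mb and cM spans, and the proportion of the map
covered, merging overlapping block intervals per LG before summing.
`place_features()` anchors external sequences by the same best-hit rule,
finds the block whose bp span contains the feature, and interpolates its
cM position linearly (by bp fraction) between the flanking mapped loci;
features at a member locus's exact bp take that locus's position, and
multi-genome placements are all reported with the smallest-e-value one
marked primary. `cluster_placements()` single-links placed features along
each LG at a configurable gap.

# The simulator and what passing tests mean

`simulate_true_map()` places loci uniformly on each linkage group;
`simulate_family()` draws each offspring one recombinant gamete per parent
per LG with Poisson crossover counts at the LG length in Morgans (Haldane
model, no interference — chosen because it keeps the simulator
analytically checkable against the mapping-function inverse; an
interference model is deliberately not claimed, as the species' true
interference regime is unknown). Segregation types are drawn from a
configurable mix whose default (10% `ABxCD`, 15% `EFxEG`, 25% `HKxHK`,
25% `LMxLL`, 25% `NNxNP`) reflects that most RADseq SNPs in an outbred
cross are informative in one parent only, with a minority of multiallelic
haplotyped loci. Genotyping errors re-draw the call uniformly among the
other classes possible for the type — the simplest model that inflates rf
estimates; missingness is independent per call. Default noise (0.5% error,
5% missing) matches what stringent RADseq filtering typically leaves.
`simulate_genome_anchors()` makes bp positions collinear with the map
(3e5 bp/cM, a typical teleost ratio) and applies inversions and
translocations with the implied true block list derived by construction;
`simulate_external_features()` drops features between block members with
interpolated truth positions.

What the simulator does *not* emulate: linked (non-Poisson) crossover
interference, locus dropout correlated with genotype (allelic dropout),
paralogous multi-locus contigs, segregation distortion with a biological
cause, or alignment noise in the hit tables. Passing the recovery tests
therefore shows the pipeline is correct under its own model assumptions
and calibrated noise — not that real data of arbitrary quality will map
this well.

# Problem sizes used in the tests

The bundled verification uses one 100 cM group with 100 loci and 150
offspring for order/length recovery (Kendall tau and relative length
error), 200 random pairs for the EM-vs-grid agreement check (grid step
1e-4), four linkage groups with two inversions and a translocation for
synteny recovery, and up-to-5-locus instances for the brute-force LP
oracle. These sizes were chosen so each property is measured at a scale
where its failure modes are visible while the whole suite stays quick to
run; the same machinery scales to study-sized inputs (thousands of loci
over 24 groups) in proportionally more time, dominated by the all-pairs
two-point stage.

# Known limitations

* No multipoint hidden-Markov re-estimation: positions come from two-point
  quantities only (the windowed WLS is a two-point compromise, not a full
  multipoint likelihood).
* Ordering at spacings below the rf resolution implied by the family size
  (about 1/(2n) per parent) is arbitrary within co-positioned clusters;
  the consensus stage exists precisely because single families cannot
  resolve these.
* The consensus LP merges two maps; merging more is a composition of
  pairwise calls.
* Genome anchoring trusts the hit table; no alignment is performed and no
  attempt is made to detect paralog-driven multi-hits beyond the bitscore
  margin rule.
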