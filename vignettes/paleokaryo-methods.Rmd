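---
title: "Methods: comparative paleogenomics with paleokaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative paleogenomics with paleokaryo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokaryo)
library(dplyr)
```

`paleokaryo` implements a single comparative framework for plant and
animal paleogenomics: stringent filtering of pairwise CDS alignments into
ortholog and paralog calls, statistical validation of collinear (synteny)
and duplicated blocks, reconstruction of contiguous ancestral regions
(CARs) and ancestral karyotypes, a chromosome-level rearrangement
calculus (whole-genome duplication, fission, fusion, inversion,
translocation), and windowed gene/transposable-element landscape
profiles. A genome-evolution simulator with a full ground-truth ledger
makes every stage testable without any external data. This vignette
explains the models, the parameters that matter, the numerical choices,
and the limits of what the simulations demonstrate.

## Homolog calling: AL, CIP and CALP

BLAST-style searches report one local alignment fragment (HSP) per row.
For a gene pair the package accumulates over its HSPs:

* **AL**, the aligned length: the sum of HSP lengths after overlapping
  query intervals are merged;
* **CIP**, cumulative identity percentage:
  $100 \times \sum \text{identities} / \text{AL}$;
* **CALP**, cumulative aligned-length percentage:
  $100 \times \text{AL} / \text{query length}$, capped at 100.

A pair is retained when both CIP and CALP reach the divergence-dependent
threshold: **70%** for genomes whose common ancestor is younger than
about 50 My ("close"), **50%** for older splits ("distant"). Three
numerical choices are deliberate:

* *Overlap merging.* Overlapping HSPs on the query are merged before AL
  is summed; each query base is attributed to the HSP with the highest
  identity fraction covering it. Without merging, CALP could exceed
  100%, which the percentage reading forbids.
* *Inclusive comparisons.* Thresholds use `>=`, so a pair at exactly
  70/70 passes. "A threshold of 70%" does not state strictness;
  inclusive is the reading that keeps boundary pairs.
* *Identity counts from percentages.* When the alignment dialect has no
  identity-count column, counts are `round(pident/100 * length)` with
  half away from zero, which is reversible to one decimal for HSPs up
  to 5 kb.

Among passing candidates, each query gene keeps, per target genome, the
hit with the highest CIP (ties: higher CALP, then lexicographic subject
id) — the highest cumulative identity over the longest cumulative
length. Reciprocal-best-hit filtering is available
(`call_homologs(..., reciprocal = TRUE)`) but off by default: one-way
best hits with deterministic tie-breaking reproduce the selection rule
as stated, and reciprocity discards co-orthologs after lineage-specific
duplication. The divergence class is configuration (a per-genome-pair
table), not inferred from the data: divergence dates come from the
literature, not from the alignments being filtered.

## Synteny blocks: chaining and CloseUp-style validation

Retained pairs are projected onto gene orders as *anchors* (rank on each
chromosome, orientation = product of member strands). Within each
chromosome pair, anchors are chained into candidate blocks: consecutive
anchors of a chain differ by 1–`max_gap` ranks on both sides and follow
one direction (direct or inverted). Chains are extracted greedily,
longest first — ties prefer the direct orientation, then the
lexicographically smallest anchor sequence — so each anchor belongs to
at most one block per chromosome pair and coverage sums never double
count. The default `max_gap = 20` genes matches the nominal cluster
length of the validation step.

A candidate block with match number $m$ (anchors) and cluster length $L$
(gene-rank span, the larger of the two sides) is **valid** when:

1. $m \ge 5$ (match number);
2. its local anchor density $m/L$ is at least **2×** the background
   density. The background is the chance co-localization rate on *both*
   chromosomes: $A \cdot L_0 / (N_a N_b)$ anchors per gene, where $A$ is
   the chromosome pair's anchor count, $N_a, N_b$ the chromosome gene
   counts and $L_0 = 20$ the nominal cluster length. A one-sided
   background (anchors per gene of one genome) would approach 1 for
   strongly syntenic genomes and reject everything; the two-sided rate
   measures how often anchors would co-occur in aligned windows by
   chance, which is what a density *ratio* must be compared against.
3. a Monte-Carlo p-value below $\alpha = 0.05$.

The null model for (3) permutes gene ranks within both chromosomes,
scattering the pair's anchors uniformly over the two rank spaces. Two
test statistics are implemented:

* **`null = "chain"` (default).** The longest gap-bounded strictly
  monotone run among the scattered anchors, compared with $m$. This is
  an *order* statistic: it asks directly whether genes "in the same
  order" on two segments could be so by chance, and it remains
  informative when most genes are anchored (where any count-in-window
  statistic saturates). When the subsequence-counting bound
  $2\binom{A}{m}/m!$ is below $10^{-6}$ the simulation is skipped and
  $p = 0$ recorded. Blocks of a pair are validated strongest-first and
  the null *peels*: each block is tested against the anchors not already
  absorbed by an accepted block, so a genuine small block is not judged
  against a neighbouring giant block's own anchors.
* **`null = "window"`.** The count of anchors falling in a fixed window
  of $L$ ranks. Its null is exactly
  $\mathrm{Hypergeometric}(N_a, L, A)$, giving a closed form
  (`window_p_closed_form()`) against which the Monte-Carlo machinery is
  calibrated to ±0.01 at 10,000 shuffles in the test suite.

Defaults: 1,000 shuffles, $\alpha = 0.05$; fewer than 100 shuffles is an
error (the p-value would be unstable at the 0.05 decision point).
Validation is deterministic given the scan seed: per-block seeds and
cached null distributions are derived from it.

Duplicated (paralogous) blocks are dated by position: a block whose two
copies both lie at positions orthologous (sharing at least one validated
ortholog-block anchor each) to the two copies of a duplicated block in
another genome descends from a *pre-speciation* duplication
(`ancestral`); otherwise it is `lineage_specific`. Coverage summaries
report anchors–blocks–percent per genome, with block spans union-merged
per chromosome before dividing by genome length.

## Ancestral reconstruction: CARs

Validated ortholog blocks are projected into a shared segment space by
*common refinement*: every block side covers the gene families inside
its rank span, and families covered by exactly the same set of blocks
form one segment. Any breakpoint observed in any genome therefore
splits segments, which keeps independently arisen junctions in
different lineages apart — at block granularity two such junctions can
look identical and would be merged.

Consecutive segments on a chromosome define an adjacency between two
segment *extremities* (head/tail, so a reversed pair joins different
extremities than a direct one). An adjacency is accepted as ancestral
when observed in at least `min_support = 2` distinct genomes — the
minimal multi-genome reading of "found at orthologous positions between
modern species": one genome cannot distinguish ancestral adjacency from
a lineage-specific fusion, two can, since an independent identical
junction requires breakpoint convergence at gene resolution. CARs are
then the maximal simple paths of this graph. Branches are resolved by
dropping the lowest-weight incident edge (ties: drop the edge whose
removal minimizes the variance of resulting path lengths, then
lexicographic); cycles are broken at their lexicographically first
segment. All rules are deterministic: a CAR set is a unique output.

Protogene counts per CAR are distinct gene families (connected
components of the homolog graph restricted to validated blocks), and
the gene-space size is the sum over families of the *shortest* conserved
CDS length — the minimal-physical-size reading of a conserved gene
space. One known limitation: with an unresolved whole-genome
duplication *predating* all sampled genomes, families span both copies
and the two duplicated regions share no gene ids but do share families;
`reconstruct_ancestor()` is therefore intended for post-duplication
(diploidized, copy-resolved) comparisons, which is how the acceptance
simulations use it.

## The karyotype event calculus

A karyotype is an unordered set of chromosomes, each a signed sequence
of ancestral segments (color = founder protochromosome, copy index
incremented by WGD). The count law is enforced structurally: WGD
doubles $n$ (a triplication step, used for the eudicot paleohexaploidy,
triples it in count arithmetic); a fission adds 1; a fusion — telomeric
(TCF, end-to-end) or centromeric/nested (CCF, insertion into the
other's interior) — removes 1; inversions, reciprocal translocations
and deletions leave $n$ unchanged. Non-reciprocal translocation is
expressed as fission + fusion, keeping the law exact; deletions remove
segments but never a whole chromosome. `classify_fusion()` recognizes
the fusion mode from color layouts (`A..A B..B` is TCF, `A..B..A` is
CCF, anything else "complex") and expands a CCF into its elementary
1 fission + 2 fusions.

`count_trace()` replays published event arithmetic on bare chromosome
numbers; the shipped lineage scripts
(`inst/extdata/scenarios/fig1_counts.yaml`) encode the plant and animal
clade histories this way. Three scripts (chicken, human, chimpanzee) are
flagged: their published fission/fusion counts do not satisfy the count
law (e.g. 30 + 1 − 3 = 28, not 33). They are shipped as printed and
`replay_lineages()` reports the mismatch rather than silently
correcting it.

`infer_min_events()` searches for a minimal scenario between two
karyotypes over the segment-conserving moves (fission, TCF fusion with
all four end joins, inversion). States are canonicalized — each
chromosome read in the lexicographically smaller strand, chromosomes
sorted — and a bidirectional breadth-first search (meet in the middle,
with a short certificate search from the meeting state) returns a
provably minimal scenario within the event budget, or an explicit
`not_found`. WGD is excluded from the search moves: it is never part of
a minimal scenario on the segment-conserved instances the search is
designed for, and it doubles the state alphabet. The heuristic mode
decomposes the start karyotype into single-segment chromosomes by
fissions and rebuilds the target by fusions; it always yields a valid
scenario, hence an upper bound on the minimum.

## Landscape profiles

`window_profiles()` tiles chromosomes with fixed windows (default
**500 kb**, last window truncated) — internally 0-based half-open for
exact tiling, reported 1-based inclusive. Genes are counted in the
window containing their *start* coordinate, so window counts always sum
to the chromosome total regardless of window size (an `overlap` mode is
available). TE coverage is computed per class (class I LTR, class I
non-LTR, class II) as the union of intervals intersected with the
window: overlapping or nested copies of one class count once, while
different classes are tallied independently, matching the separate
per-class curves of chromosome heat maps.

## The simulator and what passing tests show

`simulate_genomes()` builds a protochromosome ancestor (plant-like: 5
protochromosomes, 12,000 protogenes; animal-like: 10 and 16,000),
optionally applies shared pre-speciation events, speciates lineages with
their own event budgets, and emits gene orders, HSP tables, TE
annotations and a ground-truth ledger. Key models and their defaults:

* **Identity.** Truncated Gaussians on percent identity: close pairs
  85 ± 5, distant 60 ± 5, duplicate (WGD-age) pairs 65 ± 5 — chosen to
  straddle the 70/50 thresholds so the filter has real work to do. A
  pair's model follows its divergence *date*: cross-genome pairs whose
  copies split at a pre-speciation WGD use the older duplicate model.
* **Fragmentation.** HSP count per pair ~ 1 + Poisson(mean − 1) with
  fragments covering 95% of the query; decoy HSPs between unrelated
  genes are injected at 10% of the true-pair count around 40% identity
  (below both thresholds).
* **Gene loss.** Post-duplication diploidization removes one uniformly
  chosen copy per multi-copy family with the configured probability
  (uniform is the null model in the absence of a stated bias);
  independent per-gene loss models annotation/fractionation noise.
* **Rearrangement scale.** Random breakpoints keep at least 25 genes on
  each side (`min_segment_genes`), so no *simulated* segment falls below
  the detection scale set by the match number; shared runs that still
  end up smaller (crossing breakpoints from different lineages) are
  excluded from block-recovery recall, since no method bound by a match
  number of 5 can report them.
* **TE spatial structure.** Plant mode: 15% of 500-kb windows are
  nested class-I LTR hot-spots around 57% coverage over a ~17%
  background (overall mean ≈ 23%, maxima near 58%), plus ~3% non-LTR
  and ~5% class II. Animal mode: homogeneous ~33% non-LTR, ~9% LTR, ~3%
  class II. The generator writes its realized per-window coverage to
  the ledger, which is what profile comparisons are tested against.

Everything is reproducible from one seed, and the ledger (families,
true pairs, per-gene segment runs, per-lineage event scripts, realized
TE coverage) is consistent with the emitted files by construction.

What the simulations do *not* emulate — and hence what green tests do
not show about real data: no nucleotide sequences (identity is drawn,
not aligned), no tandem duplications or transpositions of single genes,
no gene-length or loss biases, clock-like uniform divergence within a
class, and rearrangement breakpoints away from the detection scale.
Real genomes violate all of these to some degree; the simulations
demonstrate correctness of the machinery under its own assumptions, not
robustness to every property of real annotations.

## Problem sizes and runtime choices

The test suite and the acceptance script run desk-scale studies:
three-genome simulations of ~1,200 protogenes on 5 protochromosomes
(`scale_profile(cfg, 0.1)`), 300–500 Monte-Carlo shuffles inside scans
and 10,000 where a p-value is compared against its closed form, 30
chaining-oracle instances (≤ 12 anchors, exhaustive subset enumeration)
and 50 parsimony instances (≤ 6 chromosomes, ≤ 4 events, exact search
budget 4). These sizes keep every quantity's sampling error well inside
the margins being asserted while the whole suite runs in about a
minute; the algorithms themselves carry no small-size assumptions, and
the same code paths run unchanged at full scale.
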