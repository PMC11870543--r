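---
title: "Building and characterizing pan-gene sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and characterizing pan-gene sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanGeneKit)
```

## The problem

A single reference genome under-represents the gene content of a crop
species: many loci are present only in some varieties. Given high-quality
assemblies and annotations for a panel of genomes (the motivating case is a
panel of 16 *Oryza sativa* accessions spanning the japonica, indica, aus and
aromatic groups), a *pan-gene* is a cluster of gene models from different
genomes occupying the same aligned genomic location — syntenic orthologs,
possibly joined by same-genome tandem paralogs. PanGeneKit builds such
clusters from per-genome GFF3 annotations plus cross-genome *lifted
intervals* (gene spans projected onto other genomes by whole-genome
alignment or liftover, consumed here as BED), then characterizes them:
occupancy classes, core-genome extrapolation, reference-relative
pseudo-positions, versioned stable identifiers, protein-domain variability
and enrichment, peptide-level support, and agreement with external
clusterings.

Whole-genome alignment itself is out of scope: the package ingests its
product. This keeps the clustering logic testable — the synthetic generator
(below) produces lifted intervals with known ground truth.

## Coordinate conventions

Internally every interval is 0-based half-open, the BED convention.
Conversion to and from GFF3's 1-based inclusive coordinates happens only in
`read_annotation()`/`write_annotation()`. A single internal convention
avoids the classic off-by-one drift when GFF3 gene models are intersected
with BED alignment evidence.

## Merging overlapping annotation sets

A reference genome frequently has several annotation sources that must be
reconciled into one non-redundant gene set before clustering.
`merge_annotation_sets()` merges protein-coding genes whose spans overlap by
at least 50% of the shorter gene's length (configurable) on the same strand.
The merged gene's span is the envelope of the most extreme 5' and 3'
member coordinates, its identifier comes from the highest-priority source
(ties within one source go to the 5'-most member), and all member
transcripts are retained.

Merging iterates connected-component rounds to a **fixed point**: an
envelope produced by one round can overlap a neighbour by more than the
threshold even when the original spans did not, so a single pass is not
idempotent. Iterating until the gene count is stable makes the operation
idempotent and order-independent by construction — properties the test
suite asserts on randomized inputs. The cost is that chained overlaps can
cascade slightly further than a strict original-pairs reading would allow;
with real annotation sets the second round is almost always empty.

Antisense overlaps never merge. TE-tagged gene models pass through
unmerged (they are retained at this stage because historic annotations
sometimes mislabel real genes as transposons; TE filtering is applied later,
at the cluster level, where the evidence is stronger).

## Clustering into pan-genes

`build_overlap_graph()` emits an edge between gene *a* and gene *b* (in
different genomes) when *a*'s interval lifted onto *b*'s genome overlaps
*b*'s span by at least `min_overlap_fraction` of the shorter of the two
features **and** the lifted strand equals *b*'s strand. The strand condition
keeps overlapping antisense genes out of the same cluster. Evidence in one
direction of a genome pair suffices; requiring reciprocal evidence would
only discard information and the redundancy of an all-pairs panel already
gives robustness (see the dropout experiment below). The default threshold
of 0.5 mirrors the merge rule's 50% convention; the alignment tool's own
internal threshold has no single authoritative value, so this is a
package default, exposed as a parameter.

`cluster_pangenes()` takes connected components of the edge graph —
deliberately not reciprocal-best-hit, so that tandem paralogs lifted onto
the same target locus join one cluster. Components are then checked for
validity: if two same-genome genes inside one component overlap each other
on opposite strands, the component is split, each offending gene seeding a
sub-component and the remaining members attaching through their strongest
edges (smallest accumulated `1 - overlap_fraction`). Cross-chromosome
membership is allowed by design; `flag_cross_chromosome()` reports clusters
with occupancy above 2 spanning several chromosome names, which is how
translocations (or assembly errors) surface.

Per-cluster QC (`cluster_qc()`) records the standard error of exon counts
and of CDS lengths (in amino acids) across each member gene's canonical,
longest-CDS transcript. Homogeneous clusters have SE 0; large SEs flag
clusters mixing fragmentary or mis-annotated models.

## Occupancy classes and core-genome growth

With *n* genomes, a cluster of occupancy *k* (distinct genomes with a
member) is **core** when *k = n*, **softcore** when
*floor(0.95 n) ≤ k < n*, **cloud** when *k ≤ 2*, and **shell** otherwise.
At *n* = 16 the softcore threshold is 15, the conventional
instantiation; `floor` rather than `ceiling` is used because
ceiling(0.95 × 16) = 16 would leave the softcore class empty — the
convention "95% of genomes means 15 of 16" fixes the intended rounding.

`fit_core_growth()` extrapolates the core-genome size. For each of
`n_perm = 20` seeded random genome orders it tracks the core-set size after
each genome is added (the count of clusters containing every genome added so
far — necessarily non-increasing), then fits the exponential decay

$$F_c(g) = \kappa\, e^{-g/\tau} + \Omega$$

by nonlinear least squares (`minpack.lm::nlsLM`, bounded below at zero).
Two fitting variants are provided: `tettelin` fits all permutation points
unweighted; `willenbrock` fits the per-*g* medians with inverse-variance
weights, which down-weights the noisy early points. The Willenbrock variant
is this package's own weighted-median formulation, not a reproduction of any
reference implementation. Initialization is Ω₀ = median final core size,
κ₀ = first-point mean − Ω₀, τ₀ = 1, which converges reliably on decaying
trajectories; exactly constant trajectories short-circuit to the degenerate
κ = 0 solution. The returned `growth_fit` object carries the trajectory
matrix and supports `print`, `summary`, `coef`, `predict` and `plot`.

On the default simulation the fitted Ω lands within a few per cent of the
planted core count, and is stable (±2%) across permutation seeds.

## Pseudo-positions

For sorting and display, every cluster receives a position on its **mode
chromosome** (most common chromosome among members; ties resolve to a
reference member's chromosome, then lexicographically). A cluster with a
reference-genome member on the mode chromosome takes that member's *anchor
coordinate* — defined here as the gene start, which is strand-stable in
GFF3 and matches genome-browser sorting; a midpoint would serve equally but
the choice must be fixed, and start is the convention adopted throughout.

Clusters lacking a reference member are interpolated from their
neighbourhood: with the matrix ordered by mean member anchor within each
mode chromosome, neighbour clusters at rank offsets j = 1, −1, 2, −2, …, 8,
−8 are scanned. For a genome *x* with member *gene_xi* in the cluster and
*gene_xj* in the neighbour, where the neighbour also holds a reference
member *gene_1j*, the candidate is

$$\text{pseudo\_position} = \text{pos}(gene_{1j}) + \text{pos}(gene_{xi}) - \text{pos}(gene_{xj})$$

and the candidate minimizing |pos(gene_xi) − pos(gene_xj)| across all
(x, j) wins — the nearest flanking gene in any genome gives the most local,
hence most trustworthy, offset. Ties break to the earliest genome in the
declared genome order, then the earlier offset in scan order, making the
assignment deterministic. Clusters with no candidate in the ±8 window are
flagged `fallback` and ordered after the last positioned cluster of their
chromosome. A cluster whose reference member sits on a *non*-mode
chromosome goes through the neighbour scan rather than using that member's
coordinate: the member is positional evidence for the wrong chromosome.

The test suite checks this procedure against an exhaustive independent
search over the whole offset window, and checks that when every cluster has
a reference member the assignment is the identity on the reference gene
order.

## Stable identifiers

Identifiers follow `[clade].[group].[version].panNNNNNNN` — e.g.
`Os4530.POR.1.pan0020022` — where the 7-digit series starts at 0000001 for
clusters with two or more members and at 1000001 for singletons, numbered in
matrix (pseudo-position) order. `remap_identifiers()` carries identifiers
across releases by greedy descending-Jaccard matching over member gene ids
(gene, not transcript, ids: transcript churn should not break stability).
Relations recorded: `kept`, `kept-with-series-change` (a singleton gained
members or vice versa — the series encodes current membership size),
`split`, `merged` (absorbed into another cluster's surviving id),
`retired` (no overlap remains), `new`.

## Protein domains

Domain records (InterProScan TSV) are analysed separately per namespace
(Pfam signatures vs InterPro accessions). Per cluster, the **representative
domain** is the accession present in the most distinct genomes, ties broken
by a seeded uniform draw; a cluster is *domain consistent* when every
member genome carries it. Per domain, the **domain occupancy** of a cluster
is the number of genomes whose proteins carry the domain there (counted
over each genome's designated annotation set only, so adding a second
source for one genome cannot inflate counts), and the mean over the
clusters containing the domain categorizes it: **highly variable** (< 10),
**partially variable** ([10, 15]) or **invariable** (> 15), after requiring
presence in at least 5 clusters. The strict-inequality thresholds leave the boundary
values 10 and 15 unassigned; both land in the middle category here.

TE filtering before enrichment: singletons are removed if TE-annotated in
either the domain records or a legacy TE id list; multi-genome clusters
only if *every* member is TE-flagged. Enrichment of a domain in one
occupancy class against the TE-filtered background is a one-sided
hypergeometric test (the closed form `choose(K_a, k) * ... / choose(N, k)`
is asserted in the tests), BH-adjusted across accessions.

## Evidence summaries and peptides

`summarize_by_occupancy()` joins per-gene tables (AED, log expression,
pLDDT, ortholog/paralog counts) to clusters, averages within cluster over a
designated source set (clusters lacking such members are excluded), and
reports mean/median/IQR/n per occupancy level.

`digest_and_map_peptides()` performs in-silico tryptic digestion (cleave
after K/R, not before P, up to 2 missed cleavages, length 7–50), maps every
peptide back to all proteins containing it as an exact substring (I/L are
*not* equated by default; a flag enables it), and then assigns each shared
peptide to a single protein by greedy set cover — repeatedly the protein
covering the most unassigned peptides claims them, ties to the
lexicographically smallest id. Greedy cover is the standard reproducible
protein-inference heuristic; the pooled (all-genome) database is used rather
than per-genome inference.

## Cluster-set comparison

`cluster_agreement()` pairs each pan-gene with the external cluster sharing
its anchor-genome identifier and scores the pair as
100 × matching / total, with total the number of unique identifiers in the
combined set — exactly the Jaccard index × 100, which is why the score is
symmetric in the two clusterings. Unmatched and ambiguous anchors are
first-class outputs, and both sides can be filtered (by source set, or by
identifier pattern) before scoring.

## The synthetic generator: what it does and does not emulate

`simulate_pangenome()` draws an ancestral gene order (default 1000 loci on
2 chromosomes), assigns each locus an occupancy class from the profile
(default core 0.5, shell 0.2, cloud 0.3 — core and cloud dominant, shell
rare, the shape reported for real rice panels), samples the carrier genome
subset (core: all; shell: uniform 3..n−2; cloud: 1 or 2), and lays each
genome out with a fixed 2 kb inter-gene gap so genes never overlap by
accident — clustering edges can then only come from lifted evidence, which
is the logic under test. Tandem duplications (default 1% per gene per
genome) add same-genome cluster members; inversions flip strand and reverse
the order of a gene block; translocations move blocks across chromosomes.
Lifted intervals are emitted for every cross-genome pair of genes sharing a
truth cluster, placed on the target member's span with the target locus
strand, so inverted loci yield strand-flipped evidence. Duplications are
planted only in clusters spanning at least two genomes: a tandem copy of a
single-genome locus leaves no cross-genome evidence that could ever rejoin
it, so no alignment-based method could recover it and planting it would
make exact recovery unattainable by construction rather than informative.

Evidence tables are drawn with planted occupancy gradients (AED decreasing,
expression and pLDDT increasing with occupancy, at the magnitudes reported
for real panels), proteins are identical within a cluster up to a
configurable per-genome substitution rate, and a domain catalog mixes
high-retention (invariable-like) and low-retention (variable-like)
accessions. Noise mode drops a configurable fraction of lifted intervals
and/or truncates them.

What the generator does **not** model: nucleotide sequences and alignment
error (noise is interval dropout/truncation, not mis-mapping), annotation
disagreement beyond the jittered three-source reference sets, assembly
artefacts, and realistic gene-family sequence evolution. Passing the
recovery tests therefore demonstrates the correctness of the clustering,
classification and bookkeeping logic under the stated evidence model — not
robustness to real aligner pathologies.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on 16 genomes × 1000 ancestral
loci (~10,800 genes, ~134,000 lifted intervals), which exercises every code
path at a size where the combinatorics are non-trivial while a complete
test run stays comfortably interactive; oracle-equivalence checks run on
instances small enough for exhaustive search (≤ 30 clusters, ≤ 50 genes).
All randomized stages (simulation, permutations, domain tie-breaks) take
explicit integer seeds and restore the caller's RNG state, so every result
in this document and in `scripts/acceptance.R` is exactly reproducible.
Fits bound κ, τ, Ω below at zero; a zero-variance trajectory short-circuits
the fit; per-g variance weights are floored at 1e−8 to avoid division by
zero on degenerate permutation tables.

## Known limitations

* Clustering trusts the lifted intervals it is given; systematically wrong
  liftover (e.g. paralog-swapped placements) produces confidently wrong
  clusters. The strand-validity split repairs only the detectable symptom.
* The pseudo-position of a cluster flanked by rearranged neighbourhoods is
  an extrapolation and can be locally mis-ordered; it is a sorting aid, not
  a mapping coordinate.
* Growth-curve asymptotes are only as good as the exponential-decay model;
  panels whose core size has not begun to plateau yield wide-variance Ω.
* Peptide mapping is exact-substring; it does not model missed/semi-tryptic
  peptides, modifications, or FDR control, and is intended for
  cluster-level evidence counting rather than proteomics inference.
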