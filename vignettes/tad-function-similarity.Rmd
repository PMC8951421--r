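---
title: "Methods: functional similarity of genes in TADs and spatially proximate regions"
author: "TADfunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional similarity of genes in TADs and spatially proximate regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind TADfunc, in the spirit of a methods section: what each
stage computes, which knobs matter, what the synthetic generator does and
does not emulate, and where a genuinely open design choice was resolved.

## The scientific question and the pipeline

Topologically associating domains (TADs) are self-interacting genomic
regions of roughly a megabase; the stretches between consecutive TADs are
gap regions. The package asks whether genes sharing a TAD, a gap region,
or a long-range spatial contact are more functionally similar than genes
that do not, and whether encoding "same TAD" into a gene–gene spatial
network helps a graph autoencoder learn its topology and support
neighbor-based function inference. The stages are independent S4-backed
modules (`DomainPartition`, `GoDag`, `ContactMatrix`, `SpatialNetwork`,
`GaeModel`) that `runPipeline()` chains end-to-end.

## Genomic model

Intervals are held as standard 1-based closed `GRanges`. Input readers
accept both 0-based half-open BED (`coords = "bed"`) and 1-based inclusive
tables (`coords = "inclusive"`); `inclusiveCoords()` renders the 0-based
inclusive style used in printed TAD tables, so a half-open gap
`[0, 3000000)` reads back as 0 to 2,999,999.

Gap regions are the complement of the TADs from the chromosome origin up
to the start of the last TAD: the region before the first TAD is gap 1 and
each inter-TAD interval follows. Two conventions deserve note:

* **Zero-length gaps** (abutting TADs) are dropped; retained gaps are
  renumbered sequentially and the dropped count is kept on the object
  (`droppedGapCount()`), since real TAD calls leave roughly half of all
  gaps empty and downstream statistics should not silently change
  ordinals.
* **The region after the last TAD is not a gap.** Gaps are defined only
  before/between TADs; trailing sequence is unassigned territory.

A gene is assigned to a domain only when its body is entirely contained in
exactly one TAD or gap; genes spanning a boundary, covering several
domains, or falling outside every domain are excluded with a recorded
reason. Strand is ignored throughout. Genomic distance between two genes
is the absolute difference of their anchors; the anchor is the
floor-midpoint of the gene body by default (`geneAnchors()`, configurable
to the interval start), a choice that has to be made explicitly because
interval-to-point reduction is not canonical.

## GO semantic similarity

Annotations are filtered to the six experimental evidence codes (EXP,
IDA, IPI, IMP, IGI, IEP), the three namespace roots (GO:0008150,
GO:0005575, GO:0003674) are removed, alternate ids resolve to primary
ids, unknown relationship types collapse to `is_a`, and duplicate
(gene, term) rows count once.

Term-level similarity is a Wang-style hybrid measure: a term's semantic
value is 1 at itself and decays toward the root through edge weights, and
two terms are compared through the summed semantic values of their shared
ancestors over their total semantic values. The default edge weights are
topology-dependent,

\[ w(e) = \frac{1}{0.67 + n_{\mathrm{children}}(\mathrm{parent})} + w_0,
   \qquad w_0 = 0.4\ (\texttt{is\_a}),\ 0.3\ (\texttt{part\_of}), \]

so edges under highly branched parents transmit less similarity; fixed
Wang weights (0.8 / 0.6) are available via
`termSimConfig(weights = "wang")`. The backend is pluggable because the
term measure is a stand-in for whichever semantic-similarity tool a lab
prefers; everything downstream only assumes symmetry, identity = 1 and a
[0, 1] range.

Gene pairs aggregate the term-similarity matrix by **best-match average**
(mean of row maxima and column maxima): each term's best counterpart
contributes, so the score is 1 exactly when the two term sets coincide.
The aggregation is configurable (`"max"` is also provided) because
average-of-maxima variants exist in the wild and the choice is not
testable from first principles. A gene with no term in the requested
namespace makes the pair undefined (`NA`), and such pairs are excluded
downstream with a logged count rather than imputed.

Group-level similarity (for long-range region pairs) is the symmetric
two-direction best-match average over the cross-group gene-pair matrix.
The direction of "average of the best" is ambiguous, so both directions
are averaged. A gene occurring in both groups is matched against the
*other* genes (self pairs are skipped), except when it is its own only
counterpart — identical singleton groups then score 1, the only sensible
value.

## Pair statistics

Distribution comparisons use the two-sided Wilcoxon rank-sum test with
the tie-corrected normal approximation (`exact = FALSE`), which is the
regime the test actually runs in at hundreds of pairs; significance tiers
are `***` below 1e-4, `**` below 1e-3, `*` below 0.05. Distance bins are
half-open multiples of the bin size (`floor(d / binSize)`), so a 250 kbp
pair lands in bin 1 at a 200 kbp bin size. Duplicate filtering removes
pairs with identity strictly above 90% *and* e-value below 0.01 — both
inequalities strict, so a pair at exactly 90% survives. After duplicate
removal the intra and inter sets are re-balanced to equal size by seeded
down-sampling. GESS is clipped to [0, 1]; a degenerate expression range
(max = min) is an error rather than a silent 0/0.

## Spatial networks and the autoencoder

Hi-C contacts are aggregated to a gene pair by **summing** the matrix
entries over all unordered bin pairs where one bin overlaps each gene body
by at least one base pair; each bin pair counts once even if both
orientations match. Summing raw counts is an explicit assumption (a
mean-per-bin-pair variant sits behind `aggregate = "mean"`): long genes
collect more bins and hence more contacts, which mirrors how raw contact
support accumulates. Network thresholds are **inclusive** (contacts ≥ and
distance ≥), matching the "≥ threshold" convention of the reported
settings even where surrounding prose says "larger than". Genes without a
qualifying edge are not carried as isolated nodes of a HiC-GGSI network;
the TAD-augmented network keeps every HiC-GGSI edge and adds same-TAD
pairs at or beyond the distance threshold, with per-edge provenance.

The autoencoder follows the displayed linear equations: encoder
`Z = Ã W` with `Ã = D^{-1/2} A D^{-1/2}` (zero-degree rows stay zero; no
self-loops are added before normalization, with an `A + I` variant behind
a flag), decoder `Â = σ(Z Zᵀ)`. Positive edges split 7:2:1 into
train/validation/test by floor counts with the remainder to training;
validation and test negatives are sampled uniformly from the non-edges,
disjoint from each other, and every remaining non-edge participates in
the training loss. The loss is the class-rebalanced binary cross-entropy
between `Â` and the training adjacency over all off-diagonal node pairs,
with positives up-weighted by the negative/positive ratio. Two numerical
choices matter:

* The objective is the **summed** (not averaged) cross-entropy — the raw
  rebalanced log-likelihood. Plain full-batch gradient descent at the
  configured learning rate of 0.001 over 200 epochs moves the weights
  usefully under this scaling; averaging over the ~n² entries would shrink
  the gradient by four orders of magnitude and leave the model at its
  random initialization.
* A "linear autoencoder with 2 hidden layers" is contradictory on its
  face; the implementation follows the equations (one linear map,
  d = 128), and the depth stays configurable.

Weights initialize Glorot-uniform from the seed, so training is
deterministic given the split and seed; a non-finite loss aborts with a
divergence error. AUC is the rank-based ROC area with midrank ties; AP is
step-interpolated average precision with negatives ranked first on score
ties (the conservative convention). The ten-repeat protocol re-splits
with a distinct seed per repeat and reports mean ± t-based 95% confidence
half-width (`qt((1+level)/2, n-1) * sd / sqrt(n)`).

## Function inference

Reconstructed networks keep node pairs with confidence strictly above 0.6.
For a central gene, every radius-one neighbor contributes its
(de-duplicated) terms; a term's score is the number of neighbors carrying
it — occurrence counts only, nothing weighted. Edge
confidences enter only as tie-breakers (summed confidence of the
supporting edges, then term id), never as score components. The central
gene's own annotations play no role during inference (leave-one-out
contract); they are only the evaluation truth. Top-k evaluation takes the
maximum term similarity over the k × truth grid per gene and averages over
genes used once as the center; genes with no truth or no predictions are
excluded and counted, not scored 0.

## Long-range regions

On normalized 40 kbp matrices, a region pair beyond the distance
threshold is *strong* at ≥ 10 normalized contacts and *weak* in (0, 0.2];
everything else is dropped. Genes belong to a bin on ≥ 1 bp overlap
(half-open, so a gene ending exactly at the bin start is out). Distance
between the regions of a pair is the difference of bin start coordinates.
Distance presets of 3.2 / 6.4 / 9.6 / 40 Mbp are supported in the run
configuration; group similarity ≥ 0.5 marks a pair as functionally
similar. The strong/weak thresholds are per-matrix configuration, since a
global normalization scale is not transferable across datasets.

## The synthetic generator: what it emulates, and what it does not

`simConfig()` defaults define a desk-scale positive control chosen once:

* a 10 Mbp chromosome with 10 TADs, lognormal lengths (median 0.75 Mbp,
  log-sd 0.4) — below the ~1 Mbp genome-wide average so ten TADs plus
  gaps fit, with the heavy right tail real TAD calls show; about half of
  the inter-TAD gaps have zero length, mirroring real TAD calls;
* ~300 genes (25 per TAD, 4 per non-empty gap, 2–40 kbp bodies), plus 8
  boundary-spanning genes that the assignment stage must exclude;
* one functional module per TAD: a chain of 5 increasingly specific BPO
  terms under a module branch. A gene draws a pair of terms from its own
  module's chain with probability `pIntra = 0.8` and from each other
  module's chain with probability `pInter = 0.02`, plus ~1 background
  term from a 120-term vocabulary and a couple of CCO/MFO terms. The draw
  process is identical for own and other modules, so setting
  `pIntra == pInter` removes the TAD–function association exactly — that
  is the negative control;
* Hi-C expected counts `60 · d^{-1}` in bin distance, ×4 inside TADs
  (`beta`), Gamma–Poisson overdispersed, with one planted loop between
  TADs 2 and 8 (+60 expected counts per bin pair) whose genes share one
  module; normalized counts are a global ×0.2 rescaling, enough to
  exercise the ≥ 10 / ≤ 0.2 thresholds;
* expression: one base level per module, log-normal noise (log2 sd 1.0),
  attached to genes that *realized* their module annotation — that
  realized coupling is what produces a positive correlation between
  functional and expression similarity, with decoupled genes providing
  the contrast;
* 12 planted duplicate pairs (identity > 90, e < 0.01) over a background
  of 100 sub-threshold rows.

Network-construction defaults in `runConfig()` (contacts ≥ 40, distance
≥ 0.8 Mbp, i.e. about one median TAD length) put the HiC-GGSI networks in
the regime the analysis targets: long-range loop and noise edges in the
base network, dense same-TAD blocks only in the augmented one.

Passing tests on this generator show that each stage recovers structure
it was designed to detect at desk scale — intra > inter similarity,
TAD-coherent communities, the autoencoder's preference for TAD-augmented
topology, strong loop regions with similar gene groups — and that no
stage invents structure on the negative control. They do **not** show
robustness to real-data pathologies the generator omits: mapping
artifacts and copy-number structure in Hi-C, unbalanced chromosome-wide
normalization, annotation bias and shallow-vs-deep GO term usage,
overlapping or nested TAD calls, or inter-chromosomal contact structure
(the generator is single-chromosome; the inter-chromosomal ranking is
exercised on constructed tables).

Problem sizes used by the test suite and the acceptance checks are the
generator defaults above (plus one 20 Mbp / 20-TAD configuration where the
community comparison needs more communities for statistical power); the
autoencoder protocol runs its standard 10 repeats on networks of roughly
80–100 nodes.

## Known limitations

* Edge-betweenness community detection is quadratic-ish in edges; FSNs of
  tens of thousands of edges will be slow (the package targets
  chromosome-scale, not genome-scale, FSNs).
* The autoencoder trains dense n × n matrices; thousands of nodes will
  want a sparse or minibatch variant.
* One OBO per run; dual ontology releases are deliberately unsupported.
* The term-similarity backend is a documented default, not a
  byte-reproduction of any external tool.
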