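---
title: "How markerbin bins a single metagenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How markerbin bins a single metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`markerbin` deconvolutes genome bins from one shotgun metagenome assembly
using four orthogonal signals: protein homology (taxonomy), nucleotide
composition, read coverage, and single-copy marker genes. This vignette
explains the model behind each stage, the parameters that matter, the
numerical choices we made where the design was genuinely open, and what the
synthetic test communities do and do not demonstrate.

## Assumptions

The method assumes that (i) k-mer composition is an organism-level signal:
5-mer frequency profiles are approximately homogeneous within a genome and
differ between species; (ii) coverage is approximately constant across one
genome within a single sample; (iii) single-copy marker genes occur exactly
once per genome, so duplicated markers in a cluster indicate contamination
and missing markers indicate incompleteness — but genomes are *not* assumed
to be complete, which matters for symbionts undergoing genome reduction;
and (iv) a taxonomy with NCBI-style ranks is available for the protein
homology hits, even though the organisms themselves may be unknown.

## Stage 1: kingdom partition

Each protein's hits are filtered to bitscore ≥ 0.9 × its best hit and
reduced to their LCA. Contig taxonomy is a modified majority vote designed
to resist horizontal gene transfer: ranks are scanned species → genus →
family → order → class → phylum → superkingdom; at each rank every protein
is projected to its ancestor at that rank, proteins without a node at the
rank abstain. A candidate is accepted if it is the unique plurality taxon,
holds at least half the non-abstaining votes, and a strict majority of the
abstaining ("lower-specificity") proteins are ancestors-or-self of it. If
no rank produces an answer, the contig gets the plain LCA of its proteins.

Open points we had to resolve: the vote's behaviour at an exact 50/50 tie
(we fail the rank — "a majority" is ambiguous when two taxa tie) and the
denominator of the majority (proteins *with* a node at the rank; abstainers
are handled by the ancestor-consistency proviso instead). "Kingdom" is read
as the taxdump `superkingdom` rank, so the partition keys are Bacteria,
Archaea, Eukaryota, plus `unclassified` for contigs resolving at the root.
Unclassified contigs are excluded from clustering by default
(`include_unclassified = TRUE` pools them with Bacteria); only
Bacteria/Archaea pools progress.

## Stage 2: composition, embedding, clustering

**Composition.** Canonical (strand-collapsed) 5-mers — 512 keys — are
counted per contig; windows containing ambiguity codes are skipped rather
than randomly resolved, for determinism. Counts get a pseudocount of 1,
are converted to relative frequencies and centered-log-ratio transformed.
CLR is our choice for the unspecified normalisation step: it is the
standard compositional-data transform, scale-invariant (doubling coverage
of a contig's windows changes nothing) and makes Euclidean distance
meaningful downstream. PCA reduces the 512 dimensions to 50 (component
signs fixed so the largest-magnitude loading is positive, making the
output reproducible), and Barnes-Hut t-SNE (`Rtsne`, θ = 0.5,
single-threaded) embeds the pool in 2-D under a recorded seed. Perplexity
defaults to 30; for pools smaller than 3 × perplexity + 1 rows it is
lowered to ⌊(n − 1)/3⌋ with a warning, the largest value t-SNE accepts.

**Clustering.** DBSCAN runs in the 3-D space (x, y, coverage). Coverage
enters *unscaled* by default — it is a raw third axis on the same footing
as the embedding coordinates, which makes eps interpretable on that joint
scale; `scale_features = TRUE` standardises all three axes for data with
extreme coverage ranges. `min_samples` is not dictated by the method
description; we default to 4, the classic heuristic for low-dimensional
DBSCAN, and expose it. Border-point ties are resolved toward the
lowest-id core neighbour so clustering is independent of row order.

The eps sweep starts at 0.3, steps by 0.1, and stops when the pool merges
into a single cluster with no noise (or after 50 values, a hard cap that
guarantees termination on adversarial geometry). Every cluster is scored
against the marker set; completeness = % expected markers present, purity
= % of *present* markers occurring once (the denominator is observed
markers, because uniqueness is only meaningful relative to what was seen;
a markerless cluster is vacuously 100% pure). The gate is strict:
completeness > 20 and purity > 90. The winning eps maximises median
completeness over gate-passing clusters, ties to the smaller eps. Accepted
bins are frozen; failed clusters and noise re-enter the pool, and rounds
repeat until a round accepts nothing. The pool keeps its embedding across
rounds — re-embedding happens only when a taxonomic split creates a new
pool — trading a possible re-mixing benefit for stability and cost.

**Taxonomic splitting.** The leftover pool is partitioned by ancestor at
phylum, each group re-embedded (fresh t-SNE on that group's PCA rows) and
re-clustered; leftovers pool with the contigs that had no node at the
level and descend to class, and so on to species. Going from non-specific
to specific first yields well-separated groups and tolerates the unstable
classifications that highly divergent genomes produce. This is what
separates genomes with near-identical composition *and* coverage but
different lineages.

## Stage 3: recruitment

Training rows are the binned marker-containing contigs (bins contributing
fewer than two such contigs are excluded as classes; with fewer than two
usable bins recruitment is skipped, because classification is degenerate).
Features are the 50 PCA coordinates plus coverage, optionally extended with
one binary indicator column per taxon observed at each canonical rank.
The classifier is a decision tree (`rpart`, unpruned: `cp = 0`,
`minsplit = 2`, no cross-validation or surrogates) — hyperparameters were
unstated, so we match a default unpruned CART while keeping determinism.
Confidence is estimated by jackknife: 10 trees, each trained on a seeded
50% subsample drawn *stratified* so no bin loses all its rows (a simple
random 50% draw can empty a small bin); confidence = % of trees agreeing
with the modal label, hence multiples of 10. A prediction is accepted only
at 100% confidence *and* if the contig adds no marker already present in
the target bin — this guard makes bin purity monotonically non-decreasing
through recruitment. Accepted marker-containing contigs join their bin and
the training set; rounds repeat until none is accepted, then a single final
pass assigns markerless contigs under the same 100% rule (they never enter
training, since only marker-containing contigs carry verifiable identity).

## Evaluation statistics

Given ground truth, S<sub>ij</sub> is the combined bp of bin *i*'s contigs
from genome *j*; misassembled contigs are excluded before scoring (the
loader takes a per-contig flag instead of running an assembly evaluator).
Precision = 100·Σᵢmaxⱼ/ΣΣ, recall = 100·Σⱼmaxᵢ/(ΣΣ + unbinned), F1 their
harmonic mean; per-genome F1 matches each genome to its largest-fraction
bin, and F1 recovery divides the F1 sum by 100 per reference genome
(genomes with no bin contribute 0). The hull separation statistic v
removes, per genome, embedding points farther from the group centroid than
Q3 + 1.5·IQR (linear-interpolation quartiles — the convention was
unspecified, and this is the common default), builds convex hulls, and
reports the % of total hull area not overlapped by any other hull. Overlap
areas are computed exactly: convex–convex intersection by
Sutherland–Hodgman clipping and union-of-overlaps by inclusion–exclusion
(exact because intersections of convex sets stay convex); the test suite
cross-checks against a Monte-Carlo point-in-polygon estimator. Groups with
fewer than three surviving points have no hull and are reported as skipped.

## The synthetic community generator

`simulate_community()` is first-class, tested code, and its defaults *are*
the conditions under which the package's end-to-end claims are verified:
five genomes of 300 contigs each, lognormal contig lengths (meanlog
log 4500, sdlog 0.45, floored at the 3000 bp cutoff), order-3 Markov
sequence models with Dirichlet(1)-sampled transition rows (order 3 is the
smallest order that produces the tetranucleotide-scale structure 5-mer
profiles detect; concentration 50 instead yields near-identical
strain-like genomes), a staggered two-fold coverage ladder starting at
15× (or an equal profile at 50×) with per-contig lognormal depth noise of
sdlog 0.08 — the scale of GC-bias variation on ≥ 3 kb contigs, a 100-marker
single-copy set with 10% dropout (so planted genomes are deliberately
incomplete), ~1 synthetic protein per 3 kbp whose hits point at the
genome's species with a near-top sibling hit and a far-below-window decoy,
and 2% HGT-like off-target proteins. `spike_host()` adds a eukaryotic
contamination fraction (30% in the default study community) from its own
Markov model. Everything reproduces byte-for-byte under the master seed.

What passing on these fixtures shows: the stages interlock correctly, the
gates behave as specified, host sequence is excluded, and separable
genomes are recovered essentially perfectly. What it does not show:
robustness to real assembly artefacts — chimeric and misassembled contigs,
repeat-collapsed regions, ragged coverage within genomes, plasmids and
mobile elements, or homology databases with uneven taxon coverage. Real
communities with many close strains will bin worse than these fixtures;
the strain-overlap scenario (two genomes sharing one composition model)
is included precisely to exercise the low-confidence/rejection path of the
recruitment stage rather than to claim strain resolution.

## Problem sizes and determinism

The shipped tests and the acceptance script run communities of roughly
1500–2150 contigs (≈ 11 Mbp of simulated sequence) — large enough for
t-SNE/DBSCAN geometry to be meaningful, small enough to iterate on a
laptop. All stochastic steps (t-SNE initialisation, subsample draws,
community generation) run under seeds derived from a single master seed;
two runs with the same seed produce byte-identical bin tables. Degenerate
inputs are handled explicitly: pools under 4 contigs skip embedding,
markerless pools terminate immediately with everything unclustered, empty
post-filter assemblies and empty marker sets are errors, and unresolvable
taxids are dropped with counted warnings.
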