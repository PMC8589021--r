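---
title: "Methods: dominant-scored polyploid SSR fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-scored polyploid SSR fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

## The data model and its assumptions

`ssrkit` analyses SSR fingerprints of polyploid clonal crops scored
*dominantly*: for every marker, each observed fragment length (allele)
is recorded per sample as present (1) or absent (0), because in a
hexaploid the band intensity does not reliably reveal dosage (AABBBB
and ABBBBB look the same on a gel). Loci that fail to amplify are coded
9 and treated as missing. Three consequences shape everything
downstream:

1. **Missingness is block-structured.** A locus either amplified and
   was scored in full or it failed, so missing cells come in whole
   (sample, marker) blocks. Files with a stray 9 inside an otherwise
   scored block are accepted with a validation warning, and analysis
   code (`block_normalize()`) conservatively treats such blocks as
   missing — we cannot distinguish a partial score from a scoring
   accident, and discarding the partial information biases nothing
   downstream.
2. **Allele frequencies must be estimated, not counted.** A sample
   presenting *k* distinct alleles at a marker carries them in some
   unknown dosage configuration summing to the ploidy. The package uses
   the *equal-dosage* estimator: each presented allele receives weight
   1/*k*, and group frequencies are means of these weights over scored
   samples. This is the standard simple-frequency convention for
   dominant polyploid data; it is biased toward uniformity relative to
   the (unobservable) true dosages, which is why collection-level
   heterozygosity values from different software rarely agree to the
   last digit. Samples presenting *zero* alleles at a scored marker
   carry no frequency information and are excluded from that marker
   with a flag.
3. **Shared absence is not evidence.** All similarity computations use
   the Jaccard coefficient, which ignores columns where both samples
   lack the band — two accessions are not related because neither shows
   a rare fragment.

## Statistics

Per marker, with estimated frequencies $p_i$:

* total alleles = count observed present in ≥ 1 scored sample; mean
  alleles per individual = mean presence count over scored samples
  (bounded by 1 and the ploidy);
* $H_e = 1 - \sum_i p_i^2$ (Nei's gene diversity);
* $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$
  (Botstein's informativeness). The double sum is evaluated through the
  algebraic identity
  $\sum_{i<j} 2p_i^2p_j^2 = (\sum_i p_i^2)^2 - \sum_i p_i^4$, which the
  tests verify against a literal two-index loop and against the closed
  form $1 - 1/n - (n-1)/n^3$ for $n$ equally frequent alleles. PIC ≤ He
  always, since the subtracted double sum is non-negative;
* $F_{st} = (H_t - \bar H_s)/H_t$, where $H_{s,g}$ uses group
  frequencies, groups are weighted by their number of scored samples
  both in $\bar H_s$ and in the pooled frequencies behind $H_t$, and
  markers are combined by the $H_t$-weighted mean (equivalently, the
  ratio of sums). Sampling noise can produce estimates slightly below
  zero; these are clamped to 0 and flagged rather than reported
  negative.

Missing blocks are handled *pairwise-complete* everywhere: a sample is
excluded only from the statistics of the markers it lacks, and a sample
pair's Jaccard distance uses only columns of markers scored in both.
This maximizes data use at the cost of different entries resting on
different column sets; the `n_shared_columns` companion matrix makes
that auditable, and pairs sharing no informative column are flagged
undefined rather than guessed.

## Trees, ordination, and the numerical conventions

Neighbor joining is the canonical Saitou–Nei agglomeration with the
Studier–Keppler criterion $Q_{ij} = (n-2)d_{ij} - r_i - r_j$. Two
choices the field's programs leave undocumented are fixed here for
determinism: ties in $Q$ are broken by the lowest (row, column) index
pair in current matrix order (input order, new clusters appended last),
and negative branch-length estimates — routine for non-additive
distance matrices — are clamped to zero, with a count of clamped
branches attached to the tree. On additive inputs the generating
topology and branch lengths are recovered exactly (property-tested over
random 5–8-leaf trees). Newick output quotes labels containing
characters outside `[A-Za-z0-9_.+-]`, so sample ids like
`"CIP420101|mother"` survive external parsers; the writer is in-package
because the usual phylo writers do not quote.

PCoA is classical metric MDS: double-center $-\tfrac12 d^2$,
eigendecompose, scale eigenvectors by $\sqrt{\lambda}$. Jaccard
matrices are generally non-Euclidean, so negative eigenvalues occur;
they are dropped from the percent-variation denominator and their total
magnitude reported separately. This convention affects reported
percent-variation values, which is one reason published PCoA
percentages are only approximately reproducible across programs.

## Redundancy and identity conventions

Duplicate groups at threshold $\theta$ (default 0.95 similarity, the
conventional genebank boundary) are connected components of the graph
with edges where $1-d \ge \theta$ (**single linkage**, the default):
the weakest assumption consistent with "remove all but one of each
similar set", at the price that chained groups may contain pairs below
the threshold. **Complete linkage** (cliques, via a dendrogram cut) is
available because the published collection-scale reductions depend on
the unstated grouping rule. Representatives are the lexicographically
smallest id per group, making pruning independent of row order. Pairs
with undefined distance never merge groups.

Paired verification compares presence calls over co-scored markers.
The default identity rule is exact (tolerance 0 mismatching calls):
published match/mismatch calls for clonal pairs are binary, and any
reproducible band difference in a clonally propagated pair indicates a
mixture. The tolerance is exposed because between-run scoring noise is
plausible with gel-based alleles. Pairs with fewer than `min_loci`
co-scored markers are *indeterminate* and excluded from the error
percentage rather than counted as mismatches. Which member of a
mismatching pair is the true clone is deliberately **not** decided
computationally — that adjudication needs passport and morphological
data.

Reconciliation classifies query samples against a reference collection:
declared transfers and name matches are confirmed at
`match_threshold = 1.0` (identical over co-scored columns; exchanged
clones should be exact), and unlinked queries are `unique` below
`uniqueness_threshold = 0.95`, aligned with the pruning convention. The
five natural categories do not cover an unlinked query whose best hit
exceeds the uniqueness threshold; such queries get the explicit
category `unlinked_hit` (best hit reported) so that the categories
always partition the query set.

## The simulator: what it emulates, what it does not

`simulate_collection()` generates a stated world, not a fitted one:

* per marker, base frequencies $q \sim \mathrm{Dir}(c\,\mathbf 1_A)$
  with concentration $c = 0.25$ over $A = 15$ alleles — chosen once so
  that expected gene diversity (~0.74) and mean alleles per hexaploid
  individual (~3.5) fall in the bands published for real hexaploid
  sweetpotato panels (allele counts 5–27, mean alleles/individual
  2.3–4.1, PIC 0.5–0.87);
* $K = 4$ ancestral populations (the structure reported for the crop's
  gene pools) perturb $q$ as
  $p_g \sim \mathrm{Dir}(q\,(1-d)/d)$ — the multiallelic
  Balding–Nichols construction, so the `divergence` parameter $d$ is
  approximately the expected Fst. Default $d = 0.02$, matching the
  weak differentiation reported among geographic origins; realized Fst
  on dominant-collapsed data runs lower than nominal (the collapse and
  the equal-dosage estimator both attenuate), so only monotonicity in
  $d$ is asserted, not equality;
* individual ancestries $w \sim \mathrm{Dir}(\alpha\,\mathbf 1_K)$ with
  $\alpha = 0.3$ (mostly near-pure individuals, as observed); each
  marker draws `ploidy = 6` copies from the ancestry-mixed frequencies
  and collapses to presence/absence;
* noise: whole-block dropout at 2% (typical SSR failure rate; the
  source data's rate is unpublished), optional per-call flips (no
  error model was published; this is for robustness testing only),
  clonal duplication, and — for paired fixtures — label swaps that copy
  a *different* individual's complete fingerprint, the mixing process
  that produces not-true-to-type accessions. Swap donors are re-drawn
  until they differ from the owner in ≥ 1 call, so planted errors are
  detectable by construction.

Deliberately **not** modeled: SSR mutation (no stepwise model), linkage
between markers, genotyping batch effects, and any morphological layer.
A green test on synthetic data therefore establishes that the
*computations* recover planted truth under the stated generative
assumptions — not that the generator matches any particular real
collection's error structure.

Determinism: one integer seed drives every draw; identical config +
seed gives bit-identical matrices, which the tests assert.

## Scope and verification choices

* The published supplementary collection matrix is not redistributable
  and cannot be fetched in an offline test run, so the
  collection-specific headline counts (3,075 of 5,979 retained at the
  95% threshold; 2,109 of 4,255 landraces) are not asserted; the
  acceptance suite instead replays the identical pipeline — file →
  frequencies → PIC → pruning under both linkage rules — on a synthetic
  stand-in with planted redundancy and asserts exact recovery of the
  planted structure. The packaged published per-marker table covers the
  desk-scale summaries (mean allele count 14.85, mean PIC 0.7816).
* Collection-level heterozygosity means and PCoA percent-variation
  values are checked for plausible magnitude only: both depend on
  frequency-estimator and eigenvalue conventions that differ across
  programs.
* The replicated unbiasedness check of the swap-rate estimator runs at
  40 replicates × 150 pairs (rather than 200 × 500) to keep the default
  suite inside a tight time budget; the Monte-Carlo tolerance is scaled
  accordingly.
* Simulation configs serialize as JSON rather than YAML: the
  environment provides a JSON parser out of the box and the config is a
  flat key–value record.

## Known limitations

Dominant scoring discards dosage, so all diversity statistics are
estimator-conventional rather than exact; single-linkage groups can
chain below-threshold pairs together (use complete linkage to forbid
this); NJ tie-breaking makes trees deterministic but input-order
canonical rather than order-free when exact ties occur; and
reconciliation trusts its link tables — a wrong declared link is
reported as a genotype mismatch, not detected as a documentation error.
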