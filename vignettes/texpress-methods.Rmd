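---
title: "texpress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{texpress: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which knobs matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made. Every empirical statement here is one the
test suite computes; nothing is quoted from external results.

## 1. Orthology

One-to-one orthologs are reciprocal best hits (RBH) on a pairwise bitscore
table, followed by a duplicate screen: any gene that is the *unique* best
hit of two or more genes of the other species is removed, together with any
candidate pair containing it. Two conventions are ours:

* **Ties.** A gene whose top bitscore is attained by several partners has
  no unique best hit and cannot enter a pair. Ties signal exactly the
  ambiguity the duplicate screen exists for, so resolving them arbitrarily
  would be self-defeating.
* **"Best hit of many" = best hit of ≥ 2.** The minimal reading; a higher
  threshold would pass some duplicated structures through.

Each pair carries `len_a`, `len_b` (per-species total exonic length, the
union of exon intervals so overlapping annotations are not double-counted)
and their arithmetic mean `L̄`, the *effective length* used for
cross-species correction.

## 2. Cross-species differential expression

The central difficulty is that the two species' annotations disagree about
transcript length, so raw counts are not comparable across species even for
a true one-to-one pair. The chain is:

1. **Length correction**: `corrected = counts × 1000 / L̄` — counts per
   kilobase of the pair's mean exonic length. Linear in counts by
   construction.
2. **Expression floor**: each corrected column is scaled to one million
   (corrected CPM); a pair below 1 in *every* sample is set aside and
   re-enters the results as a non-DEG. Applying the floor before TMM keeps
   the trimmed-ratio estimate away from the zero-inflated low tail.
3. **TMM**: per-gene log2 ratios against a reference column, trimmed 30%
   on M and 5% on A, averaged with inverse approximate-binomial-variance
   weights; factors are rescaled to geometric mean 1. Genes with a zero in
   either sample are excluded from the trim set. With fewer than 10 usable
   genes the factor falls back to 1 with a warning.
4. **Dispersion**: a single common NB dispersion, the median over genes of
   the within-group method-of-moments estimate `max(0, (s² − m̄)/m̄²)` on
   factor-adjusted counts, averaged over the two species groups. With 4
   replicates per group this is the simplest defensible choice; tagwise
   shrinkage would be the natural extension. The estimator is biased
   slightly low in small samples (the median of a right-skewed per-gene
   statistic); the test suite checks it lands within [0.1, 0.3] for a true
   0.2 and that downstream null behaviour is sound, which is the property
   that actually matters.
5. **Exact test**: counts are scaled to equal pseudo-libraries (the
   geometric mean of effective sizes), summed per group, and the test
   conditions on the total: group-A sums are NB with size `n/φ`, so the
   conditional law of the split is computed directly (binomial when
   `φ = 0`). The two-sided p-value sums all outcomes whose conditional
   probability is at most the observed one, with a `1 + 1e-7` relative
   tolerance so floating-point ties behave like ties.
6. **Multiplicity**: BH within each developmental stage separately (the
   stages are separate questions, 4 vs 4 each); DEGs at `q < 1e-5` get a
   direction from the sign of the fold change.

PCA for sample QC runs on `log2(corrected CPM + 1)`, gene-centered. The
transform is our choice — the upstream description does not fix one — and
is stated here precisely because printed variance fractions depend on it.

## 3. Profile clustering

Genes that are DEGs in ≥ 1 stage with TPM mean > 1 and variance > 1 (across
all 16 samples) are summarized as the 4-vector of per-condition mean TPM
(A-L4, A-YA, B-L4, B-YA), Z-scored with the n−1 denominator. Using
condition means rather than all 16 samples is our choice: the object being
clustered is the shape of the species-by-stage profile, not replicate
noise.

k-means uses k-means++ seeding with Lloyd iterations, best of `n_restarts`
by within-SS, deterministic given a seed. The number of clusters comes from
the gap statistic: `gap(k) = mean_b log W*_kb − log W_k` over B reference
datasets drawn uniformly over the per-dimension range of the data (original
feature space; a PCA-rotated box is available behind `reference = "pca"`),
`s_k = sd_b(log W*) √(1 + 1/B)`, choosing the smallest k with
`gap(k) ≥ gap(k+1) − s_{k+1}`. We do not claim this reproduces any
particular published cluster count on real data — reference space and
selection rule are exactly the kind of library-default details that differ
between implementations.

Cluster labels are arbitrary; all evaluation uses partition agreement
(adjusted Rand), never label identity.

## 4. TE insertion-site classification

The gene region runs from the first CDS base to the last CDS base — UTRs
are unannotated in one species, so CDS bounds are the only cross-species
currency. Six strand-aware regions follow: CDS; 2,000 bp upstream of the
first CDS; introns (gaps between CDS intervals, *not* exon gaps, for the
same annotation-asymmetry reason); 2,000 bp downstream of the last CDS; its
0–200 bp head (possible 3′UTR); and the 200–2,000 bp remainder. The
2,000-bp flank mirrors the observation that cis-acting sequences in these
nematodes concentrate within ~2 kb of the coding start.

Conventions: coordinates are 0-based half-open internally (GFF3 converted
on read/write); ≥ 1 bp of overlap counts, so a boundary-straddling TE is
recorded in every region it touches; flanks are truncated at chromosome
ends but *not* at neighbouring genes (no neighbour-masking rule is part of
the contract, and one TE may legitimately annotate several genes). A
DOWN200 record always implies a DOWN2000 record — an interval fact the
suite asserts.

## 5. Conserved-TE calling

Evidence that a reference TE is present at the same position in a
population is a read that continuously spans a TE boundary. Concretely, for
each boundary a 20-bp window (10 bp inside + 10 bp outside) is examined and
a single mate's aligned blocks must leave at most 4 window positions
uncovered ("a gap below 5 bp in the total 20 bp"); deletions, splice gaps
and unaligned window positions all count as uncovered. Support is evaluated
per single mate — two mates cannot jointly satisfy one boundary. Either
boundary suffices. Before any of this, read pairs with an unmapped mate or
with both mates' extents fully inside annotated repeats are discarded;
"uniquely mapped" is delegated to an input flag since no MAPQ cutoff is
part of the contract.

A population is present when ≥ 1 line of that population contributes a
supporting read (`min_lines` exposes the stricter per-line rule, which the
contract leaves open); a TE is conserved when present in *all* populations.
TEs shorter than 10 bp get inside-truncated windows and are flagged —
another contract gap resolved explicitly.

## 6. Enrichment tests

For each condition (stage × direction × focal species) and each
(region × TE type), ortholog pairs are cross-classified: rows are "TE of
this type in this region only in the focal species" versus "no such TE in
either species" — pairs with the TE in both species (or only in the other
one) are *excluded*, not pooled into the without-TE row — and columns split
by DEG direction. Fisher's exact test uses the "probability ≤ observed"
two-sided rule with a `1 + 1e-7` tolerance. The reported odds ratio is the
sample cross-product ratio with a Haldane–Anscombe +0.5 on all cells only
when a zero cell exists; it is *not* the conditional MLE some tools print,
a difference that matters for small tables and is therefore documented
rather than hidden. Zero-margin tables return p = 1 flagged degenerate.

Gene universes guard against confounding: non-CDS scans use only pairs
where neither species has any TE (any type) in the CDS; the 200–2,000-bp
downstream scan additionally drops pairs with any TE in the 0–200-bp
window. BH runs within each (stage × focal × direction) condition across
the region × type scan; splitting directions into separate families is our
reading of the two reported directions being separate questions.

The cluster scan is analogous with clusters in place of directions, over
the clusterable-gene universe, BH across the whole scan.

## 7. The synthetic-data generator

The generator emulates *post-mapping structures only*: gene models, TE
intervals, counts and aligned blocks. It does not simulate nucleotide
sequence, sequencing error, mapper behaviour, multi-mapping, or fragment
length — so a green test establishes correctness of the analysis chain,
not robustness to upstream artefacts.

Defaults mirror the emulated study design: 2 species × 2 stages × 4
replicates (16 samples); 8 populations of the focal species; 150-bp reads;
planted DEGs at |log2FC| = 2; NB dispersion 0.05 (a typical bulk RNA-seq
value for inbred lines); baseline means log-uniform over [20, 500] counts.
Genes sit on a 1-Mb grid, one chromosome per 100 genes, so 2-kb flanks
never collide unless `crowding` is requested; true pairs share an identical
CDS structure while species B gains a non-coding exon (`len_b_factor`,
default 1.25) precisely so the length correction has something to correct.
Decoy genes come in blocks of two per species arranged so one B gene is the
best hit of two A genes, exercising the duplicate screen; at very small
`n_genes` the block count floors to zero.

Planted truth is decided once (`plan_deg_truth()`), deterministically from
the seed, so TE placement (optionally enriched into true higher-in-A DEGs
at a configured odds ratio) and count simulation agree. All randomness
derives from one seed; identical configurations give byte-identical output
files.

One generator subtlety is worth recording. Reads near one TE can
accidentally span a *different* TE's boundary, which would make an absent
TE look present. Non-spanning reads (boundary-stopping and gapped decoys,
anchor mates) are therefore placed support-free against every TE boundary,
shifted or shortened as needed, and skipped when no clean placement exists.
Spanning reads for present TEs are exempt — their support is the point —
so in mixed conservation patterns two TEs closer than ~half a read length
can still cross-talk; the recovery guarantees hold for non-abutting TEs,
which the default landscape produces. With abutting TEs (boundaries within
10 bp) no read can distinguish the two boundaries even in principle.

## 8. Numerical and degenerate-input choices

* Interval arithmetic merges overlapping intervals before any length or
  region computation.
* Exact-test and Fisher tie handling use a `1 + 1e-7` relative tolerance;
  the oracle tests run at 1e-10 absolute agreement.
* Empty k-means clusters trigger a fresh k-means++ seeding of that restart
  (up to 20 attempts).
* All-zero count columns, zero-exonic-length genes, missing ortholog pairs,
  unknown regions, empty comparison groups and zero populations raise
  informative errors rather than propagating NaN.
* `kmax` above the number of profiles is clamped with a warning; fewer than
  10 TMM-usable genes fall back to unit factors with a warning.

## 9. Known limitations

* Common (not tagwise) dispersion; no empirical-Bayes moderation.
* The NB exact test rounds group pseudo-sums to integers; with very small
  libraries and strong factor imbalance this discretization is visible.
* The gap statistic at `kmax = 20` with `B = 100` is the dominant runtime
  cost of a full pipeline run; the demo configurations scale B down.
* Conserved-TE calling addresses only reference-genome TEs; non-reference
  insertions (present in populations, absent from the reference) are out of
  scope, as is split-read breakpoint discovery.
* GO enrichment, de novo repeat discovery and read mapping are explicitly
  out of scope; inputs begin at count matrices, annotations and aligned
  blocks.
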