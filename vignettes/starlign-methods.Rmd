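---
title: "Methods and design of starlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of starlign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starlign)
```

`starlign` implements center-star multiple sequence alignment with two
pairwise engines (Smith–Waterman for proteins, keyword-tree anchoring for
highly similar nucleotides), reference-based SPS/CS quality scores, and a
cluster-then-merge neighbor-joining pipeline. This vignette records the
models, the tunable parameters, and the design decisions that were genuinely
open, so a reader can judge what the package computes and what its tests do
and do not establish.

## Pairwise alignment

The local aligner fills the zero-floored dynamic-programming matrix with
substitution scores $s(a,b)$ and gap penalties $W_k$ for a gap of $k$
columns, and traces back from the maximal cell until it meets a zero cell.
Two choices deserve note:

* **Gap model.** $W_k$ is linear, $W_k = k\,g$ with $g > 0$. Under a linear
  penalty the maxima over all gap lengths in the recurrence collapse to
  single-step moves, because $H_{i-1,j} \ge H_{i-1-k,j} - k\,g$ holds by
  induction once the gap branch is part of $H$ itself; the fill is therefore
  $O(1)$ per cell. Affine gaps are deliberately out of scope. Defaults:
  $g = 2$ for both nucleotide and protein schemes; match $+2$ / mismatch
  $-1$ for nucleotides, BLOSUM62 for proteins; wildcards (`N`, `X`) score 0
  against everything. These are conventional desk values, not calibrated
  constants — both the matrix and $g$ are arguments.
* **Determinism.** Traceback prefers diagonal, then vertical (gap in the
  second sequence), then horizontal moves; among equal maximal cells the
  lexicographically smallest $(i,j)$ wins. This makes every alignment, and
  hence every downstream MSA, byte-reproducible.

A local core is extended to the *full-length* pairwise alignment the
center-star merge needs by placing the unaligned prefixes and suffixes
end-gap-free: the shorter flank is padded with gaps at the outer edge, and
flank residues are not scored. This is the minimal deterministic completion
of a local aligner into a global-shaped row; nothing in the score depends on
it.

## Center-star MSA

Every non-center sequence is aligned against the center; each pairwise
record stores where spaces were inserted after which center position
(position 0 meaning "before the first residue"). Records merge by
elementwise maximum into a gap profile — a commutative, associative monoid
with the all-zero profile as identity — and each sequence is then projected
through the profile, padding its own insertion blocks with gaps
(left-justified within a block). The final column count is always the center
length plus the summed profile, which the tests check exhaustively.

**Center selection** for proteins is an open design point: the exact
criterion ("most similar to all others") costs a quadratic number of
Smith–Waterman runs. The default is a k-mer vote ($k = 3$): each sequence
scores the summed count of distinct k-mers it shares with every other
sequence, and the arg-max (ties to the smallest index) becomes the center.
An exact all-pairs-SW mode is available for small inputs. Both are declared
approximations of the same intent. For highly similar nucleotide data the
first sequence is the center by rule.

## Keyword-tree acceleration

For similar nucleotide families the center is partitioned into consecutive
segments of `seg_len` residues (default 15 — long enough that chance hits
are rare at genome scale, short enough that a segment usually survives ~1%
divergence; the final remainder is kept). Segments are indexed in a trie
with breadth-first failure links, so one left-to-right scan of a query
reports every exact occurrence of every segment.

The matches are then **chained**: the package keeps the subset of matches
with maximum total matched length that is strictly increasing and
non-overlapping in both coordinates, computed by a quadratic
longest-increasing-subsequence dynamic program with ties broken toward
earlier offsets. No chaining rule is canonical here; maximum anchored length
was chosen because it directly minimizes the residual DP area, and the
implementation is verified against exhaustive enumeration over all valid
chains. Anchors are copied verbatim; only inter-anchor regions are aligned
(regions empty on one side become pure gap insertions with no DP at all).
On simulated 1%-divergence data the DP cells filled are about 2% of the
full quadratic area; the test suite asserts the ratio stays below 0.2.

## SPS and CS

"Aligned to each other in the reference" is resolved through residue
ordinals, not column coordinates: test column $i$ pairs residue #p of $x$
with residue #q of $y$, and $P_{ixy} = 2$ exactly when some annotated
segment column of the reference pairs the same ordinals. $P_{ixy} = 1$ when
exactly one of the two test entries is a gap, 0 otherwise (including
dual-gap pairs). The numerator sums $S_i$ over *all* test columns; the
denominator is the reference's own pair sum over its segment columns, as
the formula states. CS is normalized by the number of reference segment
columns: with any other denominator a perfect alignment would not score 1,
which would contradict the score's defining property. No post-hoc clamping
is applied anywhere; the [0,1] bounds are structural for fully annotated
references, and the unit tests exercise them only in that regime.

## Distances, clustering, and the merged tree

"Functional distance" between alignment rows is the gapped p-distance:
differences divided by columns with a residue in at least one row, one-sided
gaps counting as differences, dual-gap columns excluded. A Jukes–Cantor
transform is available behind a flag but off by default, since the
clustering only needs relative distances.

Clustering follows a sample-then-assign scheme: a fraction (default 0.1) of
rows is sampled with a fixed seed, greedy leader clustering on the sample
(joining radius = median sampled pairwise distance) seeds the clusters, and
all remaining rows join their nearest seed. Rebalancing is two-sided:
clusters below `min_cluster_size` (default 2) merge into the cluster with
the nearest medoid; clusters above `max_cluster_frac`·n (default 0.1) are
re-split by leader clustering at half their median internal radius, with a
deterministic chunk split as the terminal fallback when a cluster of
identical rows cannot be separated. The published description of this
rebalancing step is ambiguous; the interpretation above (merge the small,
split the large) is this package's reading, recorded here rather than
claimed as canonical.

Neighbor joining itself is the standard $Q$-criterion agglomeration with
three deterministic refinements: ties pick the smallest index pair; negative
branch estimates are clamped to zero with the deficit moved to the sibling
branch (so path lengths are preserved); distances produced by the reduction
step are floored at zero. On additive matrices none of the refinements
fire, and the tests require exact recovery (topology, and path lengths to
1e-9) of 100 random trees with up to 8 leaves.

The cluster subtrees merge over a backbone: a neighbor-joining tree of the
cluster medoids, in which each medoid leaf is replaced by its cluster's
subtree rooted at the medoid's attachment node — the medoid stays a leaf
inside the graft, and the backbone branch length becomes the connecting
edge. How inter-cluster distances should feed this merge is not specified
anywhere; the medoid backbone is this package's choice, validated by the
clade-monophyly tests below. `build_tree(..., single_cluster = TRUE)`
bypasses the whole division and reproduces plain neighbor joining byte for
byte.

## The synthetic-data generators

`generate_dna_family()` emulates within-species genome sets: a uniform
random ancestor of length $m$, per-site substitutions with probability
`sub_rate` (default 0.01, i.e. ~1% divergence from the ancestor), and rare
indels (`indel_rate` 0.001 per site, lengths uniform on 1..3) placed between
ancestor positions and never inside an earlier indel, which keeps the true
alignment single-pass constructible. `generate_protein_family()` uses the
same machinery with BLOSUM62-biased substitutions and higher default rates
(0.05 / 0.005), emulating divergent families. `generate_clades()` is
substitution-only (so its truth alignment is gap-free), with clade ancestors
at `between_rate` from a root and members at `within_rate` from their clade
ancestor.

For two lineages at per-site substitution rate $s$ with uniform replacement,
the expected p-distance is $1 - [(1-s)^2 + s^2/3]$; the generator-soundness
test requires the observed mean pairwise distance to sit within three
standard errors of this value (the single-pair standard error
$\sqrt{d(1-d)/m}$ is used, a conservative bound since pairwise distances
sharing a member are positively correlated).

What the generators do *not* emulate: rate heterogeneity across sites,
codon structure, inversions or rearrangements, sequencing error, and
realistic base composition. Tests passing on these fixtures therefore
establish correctness of the algorithms under their stated models — not
alignment accuracy on real genomes.

## Problem sizes and limits

The test suite runs at deliberate desk scale: exhaustive Smith–Waterman
verification over every sequence pair up to length 6 on a two-letter
alphabet; 50 random families for the center-star invariants; a 50-sequence,
2000-base similar family for the keyword-tree path; 200 random match sets
for chaining; 100 additive matrices for neighbor joining; and 200 taxa in
four clades for the divide-and-conquer tree. These sizes were chosen so the
full suite completes in about a minute while still exercising every
code path at meaningful scale.

Known limitations: no affine gaps; the center-star heuristic carries its
usual worst-case approximation behavior on divergent data; segment
anchoring assumes high similarity (at high divergence it degrades to plain
center-star work); the executor's `workers` backend uses process forks and
provides partition-independence guarantees, not speedups on a single CPU;
and SPS can exceed 1 on adversarial inputs with sparse segment annotation
(extra all-gap test columns add one-point pairs to the numerator only) —
the score is reported exactly as defined, without clipping.
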