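---
title: "Clustering conserved regions without alignments: the methods behind coreClust"
author: "coreClust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering conserved regions without alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreClust)
```

## The problem

Grouping proteins by shared domains normally requires all-against-all
sequence comparison, which scales quadratically and depends on expensive
alignments. coreClust takes a different route: given a set of proteins in
which *conserved regions* (domain instances, either curated coordinates or
the output of a de-novo detector) have already been marked, it clusters the
regions themselves - and, by replacing each region with its parent protein,
produces possibly overlapping protein clusters - using only exact k-mer
content and hashing. Two copies of the same domain in different proteins
are expected to be highly similar but not identical, which is exactly the
regime where min-wise hashing of k-mer sets works.

## Min-wise hashing and the (k,c)-sketch

Each region is reduced to its set of length-$k$ amino-acid words (default
$k = 6$), encoded as integers in base 25 over a fixed 25-letter alphabet
(the 20 standard residues plus B, O, U, X, Z in ASCII order; the order is
part of the on-disk contract because sketches must be reproducible across
runs). A hash function $f(x) = (a x + b) \bmod p$ with $p$ prime - the
classical practical substitute for a min-wise independent permutation -
induces an ordering on the terms, and the *(k,c)-sketch* of a region under
$f$ is the tuple of the $c$ terms with the smallest hash values (default
$c = 2$), sorted by hash value with ties broken toward the smaller term.
Two regions are *candidate-similar under $f$* when their sketches are equal
as ordered tuples. For $c = 1$ the probability of sketch equality equals
the Jaccard similarity of the k-mer sets; larger $c$ makes a single
function more conservative, and using many independent functions recovers
sensitivity.

Two numerical choices deserve a note:

* **The prime.** All arithmetic is done in double precision, exactly: the
  default modulus is the Mersenne prime $p = 2^{31} - 1$ and the
  multiplication $a \cdot x$ is split into 16-bit halves so that every
  intermediate stays below $2^{47}$, far inside the $2^{53}$ integer range
  of a double. The modulus comfortably exceeds the k-mer code space
  ($25^6 \approx 2.4\times 10^8$) and any region-registry space used here.
  What matters is only that hash collisions between distinct terms are
  rare; occasional collisions can at worst promote a wrong term into a
  sketch, and the second level plus community detection absorb such noise.
* **Sketches store terms, not hash values.** Bucketing regions on the
  minimizing terms themselves (rather than on their hash values) makes the
  two levels symmetric and immunizes bucket keys against cross-term
  hash-value collisions. Term sets with fewer than $c$ elements yield a
  shorter sketch; the bucket key encodes the exact tuple, so short
  sketches only ever match equally short sketches, and empty term sets
  yield no sketch at all (the node is skipped for that function).

## Two-level similarity graphs

For each hash function independently, regions are bucketed by their exact
sketch tuple and every bucket of size at least two contributes all pairwise
edges (a clique). Buckets from different functions are never merged before
edge generation; the union over functions is then consolidated into a
simple graph - at most one edge per pair, no record of multiplicity kept
for clustering (an optional per-edge provenance of contributing function
indices is available for inspection).

A single level of sketching produces false positives. Instead of hashing
first-level sketches again, the second level hashes each node's *neighbor
set* in the consolidated first-level graph: node identifiers are mapped to
integers through a fixed sorted registry, each node's term set is its set
of neighbor codes, and the same sketch/bucket/clique machinery runs with a
hash family generated from a different seed (`seed + 1`). Nodes that share
most of their neighbors tend to share second-level sketches; spurious
first-level edges rarely survive. The second-level graph is the input to
community detection. Isolated first-level nodes have empty term sets and
stay isolated.

### Incremental growth

The driver grows the hash family one function at a time, so the graphs are
built incrementally. The family constructor draws coefficients
sequentially from a seeded RNG, making a family of size $n$ a prefix of the
family of size $n + 1$; level-1 sketches are therefore computed only for
added functions and the level-1 edge set grows monotonically. Level-2
sketches are *not* monotone - new level-1 edges change neighbor sets - so
the store keeps each node's neighbor snapshot and recomputes level-2
sketches, across all functions, exactly for the nodes whose neighborhood
changed. The result is identical, node for node and sketch for sketch, to
a cold build at the larger family size; the test suite asserts this
equality including the cached stores and the downstream clustering.

## Community detection

Clusters are Louvain communities of the second-level graph, driven by the
modularity

$$Q = \frac{1}{2m}\sum_{i \in V} e_{i\to C(i)} -
      \sum_{C \in P}\left(\frac{a_C}{2m}\right)^2$$

with $m$ the total edge weight, $e_{i\to C(i)}$ the weight between node
$i$ and its own community, and $a_C$ the total degree of community $C$.
The implementation is the standard two-phase scheme: a local-move phase
sweeps nodes in seeded-shuffled order, moving each to the neighboring
community with the largest strictly positive gain, and stops when a full
sweep gains less than a threshold (default $10^{-7}$, applied to the summed
gain per sweep); communities are then contracted to super-nodes with
intra-community weight as self-loops (counted twice in degrees, which is
what makes $Q$ invariant under contraction - asserted to $10^{-12}$ in the
tests), and the phases repeat until no node moves, with a configurable cap
of 20 aggregation levels as a safety net. Determinism is part of the
contract: ties among equal-gain target communities go to the lowest
community label, and the sweep order is derived from the run seed, so
identical inputs give identical partitions. An edgeless graph (or $m = 0$
generally, where $Q$ is defined as 0) yields singleton communities.

Greedy local moves can land in a sweep-order-dependent local optimum,
noticeably so on small graphs (reference implementations show the same
behavior). `louvainCluster()` therefore runs a configurable number of
independently seeded restarts (default 5) and keeps the
highest-modularity partition, with ties to the earliest run - still fully
deterministic given the seed. On exhaustively enumerable graphs this
reliably reaches at least 95% of the optimal modularity, which the tests
assert.

## The termination statistic

Two clusterings $X$ and $Y$ are compared with a cluster-size-weighted,
two-sided F1. For each cluster $X_i$, precision and recall against its
best counterparts in $Y$ are

$$precision(X \to Y) = \frac{\sum_i |X_i| \max_j |X_i \cap Y_j|/|Y_j|}
 {\sum_i |X_i|}, \qquad
 recall(X \to Y) = \frac{\sum_i |X_i| \max_j |X_i \cap Y_j|/|X_i|}
 {\sum_i |X_i|}$$

$F1_{X \to Y}$ is their harmonic mean (defined as 0 when both vanish, a
convention the formulas leave open), and the reported score averages both
directions, which penalizes trivially over-complete clusterings that would
score perfectly one-sided. Before either direction is computed, both
clusterings are filtered to clusters of at least `minClusterSize` members
(default 10); members of removed clusters do not re-enter elsewhere. The
filter counts whatever the clustering holds - regions at the region level,
proteins at the protein level. Overlapping clusterings are legal input:
the formulas involve only set sizes and intersections.

## The iterative driver

How many hash functions are enough depends on how conserved the input
families are, so the driver chooses the number adaptively. Clusterings are
computed at family sizes $h_{start} - d, \ldots, h_{start}, h_{start}+1,
\ldots$ (defaults $h_{start} = 41$, step 1); from $h = h_{start}$ on, the
current region clustering is compared with the one obtained at $h - d$
(default $d = 40$), and the loop stops as soon as the average weighted F1
strictly exceeds $\tau$ (default 0.9) - the clustering has stabilized, and
the last one generated is the output. The sizes below $h_{start}$ are
warm-up: they exist so every comparison partner exists from the first
checked size onward, and no termination test runs there. A safety cap
`hMax` (default 500) flags non-convergence instead of looping forever.
Larger $d$ or $\tau$ delays termination and smooths over the F1
fluctuations that small data sets show when a single added function
rearranges a few clusters. With a comparison step larger than 1, `d`
should be a multiple of the step or no comparison partner will ever be on
the grid. Clustering history is evicted beyond the last
$\max(d, 60)$ sizes to bound memory while leaving room to explore larger
lags.

The termination check always uses the non-overlapping region clusters;
only after termination does the driver replace each region by its parent
protein (deduplicating within clusters) to produce the overlapping protein
clustering. Louvain runs cold at every size with a seed derived
deterministically from the run seed and $h$, so a full run is reproducible
to the byte, and the clustering emitted at the terminal $h$ equals what a
cold start at that size would produce.

## The synthetic generator

Real benchmark inputs for this method are curated domain annotations at
database scale. For validation the package instead generates data with
known structure: per family a random consensus of `regionLength` standard
residues is drawn; each copy mutates every site independently with
probability `mutationRate`, substituting uniformly among the 19
alternative residues (no substitution matrix - the method senses only
exact k-mer matches, so transition biases would not change what is being
tested); copies are implanted at random non-overlapping offsets into
background proteins with uniform residue composition; and optional
architecture tuples create multi-domain proteins carrying one copy of each
listed family. The expected per-site identity between two copies is
$(1-\mu)^2 + \mu^2/19$, which the tests verify by Monte Carlo along with
the k-mer-level consequences (identity at $\mu = 0$, near-zero Jaccard at
$\mu = 0.5$).

The generator's defaults are the package's study conditions: 20 families
of 30 copies, 120-residue regions, $\mu = 0.05$, 620 host proteins of 300
residues, one two-family architecture protein. At these conditions the
driver with default parameters terminates well before the cap and recovers
the planted families essentially perfectly (the acceptance suite requires
F1 $\geq 0.9$ against ground truth on at least 4 of 5 seeds, and that the
two-family protein appears in two protein clusters). Problem sizes in the
test suite are chosen to keep a full run in the hundreds of regions - 602
regions converge in about a minute on one core - which exercises every
code path of the method at realistic per-family copy numbers.

What the synthetic model deliberately omits: indels (real domain copies
drift in length; exact k-mer matching tolerates them only between, not
across, windows), biased residue composition, substitution-matrix
structure, and regions whose boundaries are wrong by a detector's error.
Passing at these conditions demonstrates the machinery - sketching,
bucketing, two-level filtering, community detection, termination - not
performance on any particular curated database.

## Degenerate inputs and edge conventions

* Regions shorter than $k$ have no k-mers, no sketch, and stay isolated;
  they surface as singleton clusters (typically removed by the size filter
  during comparisons but retained in output files).
* Overlapping *input* regions on the same protein are kept as independent
  nodes; nothing in the method assumes disjointness.
* Multi-part domains should arrive as separate rows and are treated as
  separate regions.
* A pair of near-identical regions with no *other* similar region is a
  blind spot of second-level sketching: the two nodes' neighbor sets are
  exactly each other, their singleton sketches can never match, and the
  pair surfaces as two singleton clusters rather than one pair cluster.
  Regions embedded in a family (the intended use) do not hit this.
* The region length filter is a choice of the input kind: curated domain
  coordinates default to `minLength = 1`, machine-predicted regions should
  use `minLength = 50`, below which exact-match hits are more likely
  noise than domain.
* Bucket cliques have no size cap; a bucket above $10^4$ members logs a
  warning because edge generation is quadratic in the bucket.

## Known limitations

The linear map $ax + b \bmod p$ is 2-universal but not truly min-wise
independent: on highly structured term sets (e.g. long arithmetic
progressions of codes) the single-minimum collision rate can deviate
noticeably from the Jaccard similarity. Scattered term sets - which is
what k-mer codes of real sequences are - behave like the ideal case, and
the statistical tests target that regime.

The method senses exact k-mer matches only: families conserved below the
level where length-6 exact matches survive will fragment, and lowering $k$
trades that against random collisions. Louvain is a greedy local optimizer
- determinism is guaranteed, global optimality is not (on exhaustively
enumerable graphs the tests require at least 95% of the optimal
modularity). The termination rule compares a run against its own past, so
a pathological plateau could in principle stop early; raising $d$ or
$\tau$ is the documented remedy.
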