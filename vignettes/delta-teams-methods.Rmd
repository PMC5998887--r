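---
title: "Methods: delta-teams, Hi-C gene graphs and GO-based ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-teams, Hi-C gene graphs and GO-based ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltateams)
```

## The model

A *spatial gene cluster* is a set of genes that stay close to each other
in the three-dimensional conformation of chromosomes across several
related species. `deltateams` models each genome as an undirected
weighted graph $G = (V, E)$: vertices are genes, edge weights are
dissimilarities derived from Hi-C contact counts, and the distance
$d_G(u, v)$ between two genes is the length (sum of edge weights) of the
shortest path connecting them ($\infty$ when none exists).

For a threshold $\delta \ge 0$, a vertex set $S$ is a **$\delta$-set** of
$G$ if every pair of members is linked by a chain of members whose
consecutive distances are all $\le \delta$ — single-linkage connectivity
at threshold $\delta$. Crucially, the chains may differ between graphs
and may route *through* non-member vertices; only endpoints must be
members. A set that is a $\delta$-set in every input graph simultaneously
is a **$\delta$-cluster**, and a maximal $\delta$-cluster is a
**$\delta$-team**. In the shared-vertex setting the teams partition the
common vertex set. With gene-family labels, correspondence across graphs
is by family instead of identity: a team is then a tuple of per-graph
vertex sets with identical family spectra, each a $\delta$-set in its own
graph, maximal component-wise. Family teams need not be disjoint — one
family can belong to several teams.

Because per-graph chains may differ, thresholding the pointwise-maximum
distance matrix and running ordinary single-linkage is **not**
equivalent to this definition. The permanent regression case: $G$ the
path $a\!-\!b\!-\!c$ with unit weights, $H$ the path $a\!-\!c\!-\!b$ with
unit weights, $\delta = 1$. Then $\{a,b,c\}$ is a 1-team (each graph has
its own chain), yet in the pointwise-max matrix vertex $a$ is farther
than 1 from both $b$ and $c$. The brute-force oracle shipped with the
package therefore uses alternating per-graph component refinement, which
is faithful to the definition, and the main algorithm is tested against
it exhaustively.

## The algorithms

`find_delta_teams()` follows a divide-and-conquer scheme: a subroutine
(`smallmax()`) searches all graphs round-robin, growing in each graph a
visited set from the lexicographically smallest member by repeatedly
adding an unvisited member within distance $\delta$ of the visited set.
The first graph whose traversal exhausts on a *proper* subset has found a
maximal $\delta$-set strictly inside the working set; the working set is
then split into that subset and its complement, and both halves are
processed recursively. If every traversal exhausts on its full member
set, the working set is a $\delta$-set everywhere and — because the
recursion proceeds from larger to smaller sets — maximal, hence a team.

With families, a proper maximal $\delta$-set $B$ found in one graph
splits the search into two branches: $B$ together with the other graphs
restricted to $B$'s family spectrum, and the remainder with the
complementary restriction. The branches can overlap, so identical teams
are deduplicated by their tuple of sorted vertex sets. Before each
recursion we additionally restrict every member set to the *common*
family spectrum until stable; the restriction step of the two-branch
split can leave spectra unequal (a family surviving in one graph but not
another), and no team can contain a family missing from any graph, so
the normalization is sound and restores the algorithm's invariant for
any number of graphs.

Two numerical conventions are fixed throughout: the $\delta$ comparison
is non-strict ($\le$), including in the threshold-graph mode (a strict
reading ($<$) of the threshold-graph construction is sometimes seen but
contradicts the defining condition of a $\delta$-set, so $\le$ is used
everywhere; a `--strict-delta` toggle could expose the alternative); and
absent paths
are `Inf`, never a sentinel that could compare $\le \delta$. Vertices at
distance exactly 0 (possible via 0-weight edges) share a 0-team.
Determinism: traversals start at the smallest member id, expand smallest
ids first, and outputs are canonically sorted, so results are
byte-stable across runs.

`find_teams_via_threshold()` implements the alternative mode: each graph
is replaced by a unit-weight graph connecting pairs at distance
$\le \delta$ (all-pairs shortest paths computed once), and 1-teams are
computed there. Both modes are contractually identical and tested to
agree on every instance.

The traversal primitive deserves a note: a plain breadth-first search is
distance-correct only for uniform weights. The implementation satisfies
the bounded-expansion contract (return some unvisited member within
$\delta$ of the visited set) on exact shortest-path distances computed
per graph via `igraph`; the contract, not the traversal order, is what
the tests pin down.

## From Hi-C maps to gene graphs

A Hi-C map $M$ records contact counts between equally sized genomic
segments (the *resolution* $r$, in bp). Counts are closeness scores, so
they are transformed into dissimilarities in three steps.

**Normalization.** Maps from different experiments use different scales.
With $c$ the *average per-map maximum* across all maps of all genomes in
the run, every map is rescaled by $c / \max_{k,l}(M_{kl})$, so each
map's maximum becomes exactly $c$ (asserted to $10^{-9}$ relative).

**Contact to distance.** For genes in distinct segments $i, j$ the
distance is $\max_{k,l}(M_{kl}) + 1 - M_{ij}$: the densest contact gives
the smallest distance (1), an empty cell the largest finite one
($\max + 1$). Empty cells receive no other correction — except empty
*adjacent-diagonal* cells $M_{i,i+1}$, which are filled by the 1D
estimator below. Genes are mapped to segments by
$\lfloor \text{midpoint} / r \rfloor$ on 0-based half-open coordinates;
strand is ignored.

**Same-segment estimator.** Adjacent genes inside one segment have no
map cell of their own. The estimator builds on $C$, the mean non-empty
adjacent-segment count of the map: each base pair between gene midpoints
carries a relative count of $C/r$. That convention leaves open how a
per-bp *count* becomes a *distance* — read literally through the
count-to-distance transform it would score closer genes as farther
apart. The default model therefore interpolates the mean
adjacent-segment distance by the base-pair fraction,
$d = (b/r)\,(\max + 1 - C)$ for a midpoint gap of $b$ bp: it is
monotone increasing in $b$, vanishes as $b \to 0$, and at $b = r$
reproduces exactly the distance of an average adjacent segment pair.
The literal reading, $d = b\,C/r$, remains selectable as
`model = "count_per_bp"`.

The **spatial (3D) graph** of a genome connects, for every map cell
$(i,j)$, $i \ne j$, with genes in both segments, all gene pairs across
the segments (a clique per cell pair — no auxiliary segment vertices,
so no spurious zero distances between same-segment genes), plus
midpoint-ordered chains inside each segment; interchromosomal maps add
cross-chromosome edges the same way. The **sequential (1D) graph** keeps
only same-segment chains and adjacent-segment ($M_{i,i+1}$) edges:
identical one-dimensional distances, no three-dimensional shortcuts.
Edges heavier than $\delta$ may be pruned up front without changing any
team: a single edge heavier than $\delta$ cannot lie on a path of total
length $\le \delta$ when weights are non-negative.

The **spatial gain** at a given $\delta$ is the average number of genes
per 3D team that belong to no 1D team — the genes recruited only through
spatial shortcuts. Both sides are filtered to teams with at least two
genes in the reference genome: a singleton 3D team can never be inside a
size-$\ge 2$ 1D team, so averaging over singletons would report a
positive gain even for identical team lists, contradicting the intended
meaning of the statistic.

## GO-based ranking

Cluster candidates are ranked by functional coherence using the
"Biological Process" term hierarchy. For annotated genes $g, g'$ the
*GO-based functional dissimilarity* is
$$\mathit{gfd}(g, g') \;=\; \min_{(u,v)\, \in\, r(g) \times r(g')}
  \frac{p(u, v)}{\mathit{depth}(u) + \mathit{depth}(v)},$$
where $p(u,v)$ counts the nodes *separating* $u$ and $v$ on the shortest
undirected path in the DAG (identical or parent–child terms separate by
0) and depth is the shortest root path in edges. Two conventions were
genuinely open and are fixed as follows: depth is *shortest*-path depth
(longest-path depth is also common in GO work but nothing in the source
description suggests it), and the degenerate root–root pair (0/0) is
defined as 0, the shared-term limit; genes annotated only to the root
are flagged since they are trivially similar to everything.

The *cluster penalty* of a gene set $C$ within annotated genome
$\mathcal G$ is
$$\phi(C) = \sum_{g \in C}\Big(\min_{g' \in C \setminus \{g\}}
  \mathit{gfd}(g, g') \;-\; \min_{g'' \in \mathcal G \setminus \{g\}}
  \mathit{gfd}(g, g'')\Big) \;\ge\; 0,$$
zero exactly when every member's nearest functional neighbour lies
inside the cluster. Significance is assessed against per-size pools of
uniformly drawn gene sets; the empirical p-value is
$(\#\{\phi_{\text{pool}} \le \phi\} + 1)/(N + 1)$ (ties counted
conservatively as $\le$), so the smallest attainable value is
$1/(N+1)$ — $10^{-7}$ at the publication-scale pool size $N = 10^7$. The
package default is $N = 10^5$ for desk-scale runs; tests use $10^4$.
Scoring is restricted to genes with annotations; clusters with fewer
than two annotated genes are reported unscorable rather than scored.
Reports rank ascending by p, tie-broken by ascending $\phi$, descending
size, then cluster id, flagging $p < 0.05$.

## What the synthetic data does and does not establish

The generators produce exactly the statistical features the method
consumes, chosen once and not revisited:

* `gen_team_instance()`: random graphs with a shared vertex subset
  (default 8 shared, up to 12 in tests), integer weights 1–5, private
  vertices that can carry paths, and optional family labels with a
  configurable duplication rate (0.3 in the acceptance suite).
* `gen_synthetic_hic()`: per-chromosome counts
  $\mathrm{round}(A\,|i-j|^{-\alpha})$ with log-normal noise
  ($A = 20$, $\alpha = 1$ — a decay exponent in the range reported for
  mammalian intrachromosomal contact frequencies), a 10% empty-cell
  rate, 40 kb resolution (typical of published embryonic-cell-line
  maps), and planted clusters whose segment pairs are boosted
  to a count of 100, well above background; planting optionally spans
  two chromosomes together with the corresponding interchromosomal map.
* `gen_synthetic_go()`: a random rooted single-namespace DAG (150
  terms), background genes annotated to 1–3 random terms, and planted
  modules annotated to a shared anchor term.

A green end-to-end test establishes that planted signal of this strength
is recovered at the planted $\delta$ and that planted functional modules
rank far ahead of random sets. It does not establish performance on real
Hi-C data: the generators model neither TADs, compartments, ICE-style
bias correction (out of scope — upstream of this tool), nor realistic GO
term co-annotation structure. Conversely the correctness claims (oracle
equivalence, mode equivalence, refinement monotonicity, pruning
invariance) are distribution-free properties checked exactly.

## Limitations

* Only maximal $\delta$-clusters are reported; the nested non-maximal
  solution space is exponential and deliberately not enumerated.
* The family algorithm's worst case is the product of the graph sizes;
  very large multi-genome runs are outside the desk-scale envelope.
* Only `is_a` links of one GO namespace are used; no information-content
  similarity, no multiple-testing correction (raw empirical p with a
  0.05 significance flag only).
* The single-linkage hierarchy over all $\delta$ and randomized or
  guide-tree accelerations of the search are out of scope.
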