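---
title: "Shortest-path interaction networks and hub ranking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest-path interaction networks and hub ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgnet)
```

## The analysis in one paragraph

Given (i) a typed molecular interactome — proteins, small molecules,
functional classes, complexes and cell processes connected by binding,
regulation, expression and related relation types — (ii) a table of
expression fold changes and p-values from a mutant/control comparison, and
(iii) flat gene-set annotations, `fgnet` screens the expression table for
up- and downregulated genes, connects those seed genes to biological groups
by unweighted shortest paths to form a primary network, subtracts the
subnetwork anchored on differentially expressed (DE) genes, ranks its nodes
with topological essentiality scores (Degree, Bottleneck, MNC, DMNC and the
DSS double screen), and tests network gene sets for annotation-term
over-representation. A synthetic-study generator with planted ground truth
makes every stage testable end to end.

## Differential-expression screening

A gene is called upregulated when its fold change exceeds `up_fc` (default
1.5) and its p-value is below `alpha` (default 0.05); downregulated when the
fold change is below `down_fc` (default 0.66) at the same significance.
All three comparisons are **strict**: a record at exactly 1.5, 0.66 or 0.05
is never selected. Fold changes are used on the raw ratio scale as supplied
(no log transform) and p-values are raw — this screening stage applies no
multiple-testing correction, which is the convention for candidate selection
feeding a network analysis rather than a final inference.

When the same gene appears in several source tables (e.g. two microarray
studies of the same tissue), the record with the smallest p-value wins.
This most-significant-evidence rule is our own documented choice; records
that tie on the minimal p-value but disagree on fold change are rejected as
conflicting rather than silently resolved. Externally validated genes
(e.g. RT-PCR confirmations) can be merged per direction with
`merge_curated_genes()`, which re-checks the up/down disjointness
invariant.

## Shortest-path network construction

Biological groups are named containers of interactome entities (a process,
an enzyme family, a complex). For each seed gene $s$ and each group $G$ the
builder computes $d^\* = \min_{g \in G} d(s, g)$, the unweighted
shortest-path distance on the **undirected view** of the interactome, and —
when $d^\* \le$ `max_len` — includes **all** shortest paths from $s$ to
**every** member of $G$ at distance $d^\*$. Design choices behind this:

* *All tied paths, not one.* Selecting a single path would require an
  arbitrary tie-break and make the output depend on internal orderings;
  including the full tied set is deterministic and permutation-safe.
* *Undirected walking.* The interactome mixes inherently directed relations
  (expression, promoter binding, regulation) with symmetric ones (binding).
  Paths are found on the simple undirected topology; direction and effect
  sign survive as edge attributes in the output, never as path constraints.
* *`max_len` default 4.* A length cap bounds both runtime and the dilution
  of biological signal along long paths; four steps is a conservative upper
  bound for meaningful influence chains in curated interactomes and is
  exposed as a parameter. Seeds with no group member within the cap are
  reported and skipped, never fatal.
* A seed that is itself a group member contributes only itself
  ($d^\* = 0$): distance zero admits no edges.

Group-to-group paths with no seed involved are not constructed.

### Subtraction

The subtracted network keeps exactly the relations with **at least one DE
endpoint**, and exactly the nodes incident to a kept relation. The
operation is idempotent, always yields an edge subset of its input, and
stamps each node's `de_status`. Network summaries report the mean degree
$2E/V$ both as a real number and truncated toward zero, the integer form
used in network reports (e.g. $V = 632$, $E = 2362$ gives $7.47$,
reported as seven).

## Hub and bottleneck ranking

All scores are computed on the simple undirected topology: parallel
relations between a node pair collapse to one edge, and relation direction
is ignored. This is deliberate — the scores are topological statistics, and
whether a curated source records one or three relation types for the same
physical pair should not change a node's centrality.

**Bottleneck (BN).** For every root $v$, a breadth-first shortest-path tree
$T_v$ is grown over $v$'s connected component. A non-root node $w$ is a
*bottleneck* in $T_v$ when its strict descendant count is at least $n/4$
($n$ = nodes in $T_v$; real-valued threshold, $\ge$ comparison). BN$(w)$
counts the roots for which $w$ is a bottleneck. Two pinned conventions:

* *Tree tie-break.* BFS trees are not unique; when a node has several
  predecessors one level closer to the root, its parent is the
  lexicographically smallest id. The independent test oracle applies the
  identical rule so that exact score equality is a meaningful check.
* *Root exclusion.* The root's own descendant count is $n-1$, which would
  qualify in every tree and carry no information; $v$ is never counted as a
  bottleneck of $T_v$.

Because the tie-break consults node ids, BN is guaranteed equivariant only
under order-preserving relabelings; the neighborhood statistics below are
equivariant under arbitrary relabelings.

**MNC / DMNC.** MNC$(v)$ is the node count of the largest connected
component of the subgraph induced by $v$'s open neighborhood ($v$
excluded); DMNC$(v) = E_{\mathrm{MNC}} / V_{\mathrm{MNC}}^{\,\varepsilon}$
is its density-style normalization with $\varepsilon = 1.7$ by default.
A neighborhood component with at most one node scores DMNC 0, so
DMNC$(v) = 0$ exactly when the component has no edge. The exponent is
exposed (`epsilon`) because the method family treats it as a tunable;
1.7 is the value of the original definition.

**DSS.** The double screening scheme shortlists the top $2n$ nodes by DMNC
(the factor 2 is the scheme's empirical pool multiplier, exposed as
`screen_factor`), then re-ranks that pool by MNC and returns the top $n$.
All rank orders break ties by ascending node id, making every table
deterministic. Disconnected graphs are handled per component; cross-
component pairs contribute nothing to any score.

## Over-representation analysis

For a study set of $n$ genes inside a background of $N$, a term annotating
$K$ background genes and $k$ study genes gets the one-sided upper-tail
hypergeometric probability $P(X \ge k)$ — the Fisher exact test for
over-representation (computed via `phyper`; the suite cross-checks it
against explicit binomial-coefficient sums). Terms with $k = 0$ are not
reported. Adjustment is Benjamini–Hochberg by default with Bonferroni as
the alternative; the background defaults to the annotation universe and is
overridable. Terms are flat gene sets — no ontology-graph propagation.
Significance filtering is strict (`p_adj < alpha`), with 5e-5 and 0.05 the
usual reporting levels.

## The synthetic-study generator

The generator replaces inputs that cannot be redistributed (a commercial
interactome, microarray supplements) with instances whose ground truth is
known by construction:

* **Interactome** — preferential attachment: a clique on $m+1$ nodes, then
  each new node attaches to $m$ distinct existing nodes with probability
  proportional to degree, giving exactly
  $\binom{m+1}{2} + m(n-m-1)$ edges (tested as a closed form). Defaults
  $n = 500$, $m = 2$ produce the heavy-tailed degree distribution real
  interactomes show — a few dominant hubs over a low median degree. Node
  kinds and relation types are drawn from configurable proportions
  (85% protein; binding the most common relation), with type-consistent
  directedness.
* **Planted bottlenecks** — dense Erdős–Rényi clusters (edge probability
  0.6 plus a connecting cycle, so each cluster is connected) joined *only*
  through connector nodes wired to two members of every cluster. Removing
  the connectors disconnects the graph; this is asserted on every instance,
  and the suite verifies the connector is the top BN node in 30/30 seeded
  instances (2 clusters × 15 nodes).
* **Expression** — 10% of protein nodes DE by default, fold changes exactly
  2.0 (up) and 0.5 (down) with p-values below 0.01; null genes get fold
  changes log-uniform on [0.8, 1.25] and uniform p-values. The null band
  sits strictly inside the no-call region, so screen recovery of the truth
  sets is exact rather than probabilistic — a deliberate separation
  property that turns the screening test into an identity check.
* **Annotations** — 50 terms over the protein background, one planted term
  overlapping the target set by a configurable fraction (default 1.0).
  With full overlap the planted term is the minimal-p hit by construction.

Each generator reseeds from `rng_seed` plus a fixed stage offset
(interactome and bottleneck planting +0, expression +1, annotations +2), so
every generator is bit-reproducible standalone and `simulate_study()`
reproduces exactly from one config.

What the generator does **not** emulate: literature-derived relation-type
frequencies, probe-level microarray noise, correlated expression along
pathways, and the incompleteness biases of curated interactomes. Passing
the planted-recovery tests therefore demonstrates algorithmic correctness
under clean separation, not robustness to the messiness of real data.

## Pipeline and reproducibility

`run_pipeline()` chains simulate (or file inputs) → DE selection → build →
subtract → summarize → rank → enrich from one YAML config holding exactly
one of a `simulate` or an `inputs` block (unambiguous provenance). In
simulate mode the annotation terms double as the biological groups and the
subtracted network's node set is the enrichment study set. Every
intermediate is written in the package's own text formats and round-trips
through its readers; the run manifest records the config snapshot, seed,
per-stage counts and per-file MD5 digests. The run directory is named by
seed (not timestamp) precisely so that identical seeds yield identical
manifests.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise: 200 random connected
graphs of ≤ 12 nodes for exact BN-oracle equality; 30 planted-bottleneck
instances of 31 nodes; brute-force hypergeometric checks for backgrounds up
to 60; planted-term recovery over 20 seeds at background 500 with 51
terms; shortest-path oracle checks on graphs of 30–50 nodes; and full
pipeline runs at 100–150 nodes — sizes chosen so each property is checked
exhaustively in seconds while the graphs remain large enough to exhibit
ties, disconnection and heavy tails. Scores are exact integer counts except
DMNC (floating point; compared at 1e-9 or tighter) and p-values (checked
against combinatorial arithmetic at 1e-12).

## Known limitations

* BN's lexicographic tie-break is one of several defensible conventions;
  scores on highly symmetric graphs depend on it (the oracle pins it).
* The all-tied-paths rule can include many edges on dense interactomes;
  `max_len` is the safety valve.
* Enrichment treats terms as independent flat sets; hierarchical
  annotation structure (true-path propagation) is out of scope.
* The screening stage trusts the supplied fold-change orientation and does
  no probe-to-gene mapping or normalization.
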