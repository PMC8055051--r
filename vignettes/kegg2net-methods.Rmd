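---
title: "From pathway maps to gene-only DAGs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pathway maps to gene-only DAGs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kegg2net)
```

KEGG pathway maps mix genes with compounds, reactions, links to other maps
and protein complexes. Most omics datasets, however, measure only genes (or
their products), and several downstream methods — Bayesian networks in
particular — additionally require an acyclic graph. This package converts
KGML pathway documents into directed gene-only interaction networks that
keep every direct *and indirect* gene–gene relation, offers four ways of
converting a cyclic network into a DAG, and provides the simulation and
scoring machinery needed to compare those four DAGs on expression data that
respects the network's regulatory topology.

This vignette records the models behind each stage and the design decisions
that were genuinely open, so that a maintainer can see why the code is the
way it is.

## From KGML to a heterogeneous graph

`parse_kgml()` maps each KGML `entry` to a typed node (gene, ortholog,
compound, map, group, enzyme, or other), each `relation` to one or more
links, and each `reaction` to substrate→enzyme and enzyme→product links
(mirrored again when the reaction is reversible). Three conventions matter:

* **Compound-routed relations.** A relation whose subtype names a compound
  entry is decomposed into `source → compound` and `compound → target`.
  This is what later makes indirect gene–gene paths through metabolites
  recoverable. The regulatory sign of the relation is attached to the
  `compound → target` hop while the first hop is neutral, so the product
  of signs along the two hops equals the relation's sign.
* **Undirected subtypes.** `binding/association` asserts no direction and
  emits links both ways.
* **Groups and multi-identifier entries.** A group (complex) is dissolved:
  links to or from it are lifted to every member and the group node itself
  is never emitted — keeping a synthetic complex node would pollute the
  gene-only collapse. An entry carrying several KEGG identifiers expands
  to one node per identifier, all inheriting the entry's links, because
  downstream networks are per-gene.

Ortholog (KO) entries appear in reference pathways; whether they should
count as genes depends on the user's question, so `build_hetero_graph()`
exposes `orthologs_as_genes` (default off, in which case they are ordinary
non-gene intermediates). Map entries are treated as traversable non-gene
nodes: nothing in the KGML semantics marks them as dead ends, and treating
them as intermediates is the conservative choice for *recovering* relations.

Duplicate directed edges merge; if the merged copies disagree on sign the
edge becomes `unknown`.

## The gene-only collapse

An edge `g1 → g2` exists in the collapsed network iff the heterogeneous
graph contains a directed path from `g1` to `g2` whose internal nodes are
all non-gene. Equivalently (and this is how `collapse_to_gene_network()`
computes it): `g2` is reachable from `g1` through non-gene nodes only.
A breadth-first propagation that expands only non-gene intermediates finds
all such targets in O(|V|·(|V|+|E|)) without enumerating paths; the test
suite checks it against a brute-force all-simple-paths oracle on hundreds
of random mixed graphs.

Two deliberate choices:

* **Self-loops are suppressed.** A gene that reaches itself through
  compounds would create a self-loop, which neither DAG conversion nor
  Bayesian-network scoring can accept.
* **Signs are a conservative product.** The sign of an indirect edge is
  the product of signs along the mediating routes when every hop is known
  and all routes agree; any ambiguity yields `unknown`. Sign propagation
  runs over achievable sign-products per node (a fixpoint over walks), so
  a sign-ambiguous cycle among compounds also yields `unknown` — slightly
  more conservative than a simple-path enumeration, and always safe for
  the simulator, which tolerates unknown signs by sampling a role.

Parallel indirect routes collapse to a single edge; an adjacency matrix
cannot hold multiplicities, and presence/absence is what the DAG and
scoring stages consume.

```{r collapse-example}
doc <- kgml_build(kgml_scenario(
  genes = list(e1 = "EGF", e2 = "EGFR"),
  compounds = list(c1 = "cpd:C00076"),
  relations = data.frame(source = "e1", target = "e2",
                         subtype = "compound", compound = "c1")))
collapse_to_gene_network(build_hetero_graph(parse_kgml(doc)))
```

## Four routes from a cyclic network to a DAG

All four methods return the acyclic network plus the ordered list of
removed edges; kept and removed edges always partition the input exactly,
node sets and signs are untouched, and an acyclic input is returned with
zero removals. Determinism everywhere comes from one rule: **ties are
always broken lexicographically on gene names** (under C collation, so the
result does not depend on the session locale).

The hierarchy convention is uniform: scores increase along edge direction,
i.e. an edge `u → v` asserts that `v` outranks `u`. The social-agony
formula forces this reading (an edge costs nothing only when
`rank(u) < rank(v)`), and using the same convention for PageRank and
TrueSkill keeps `remove_by_hierarchy()` a single shared primitive.

* **DFS** (`remove_cycles_dfs`): depth-first search started from every
  gene in lexicographic order; back edges — edges into a node on the
  current stack, exactly the cycle-closing edges — are removed. Fast, but
  the removal count depends on traversal order, which is why the order is
  pinned down.
* **Greedy MFAS** (`remove_cycles_mfas`): the Eades–Lin–Smyth sequence
  rule (sinks right, sources left, otherwise the max out-minus-in-degree
  node left) followed by a deterministic insertion local search on the
  sequence, run from both the greedy order and its reversal. The local
  search only ever lowers the backward-edge count, so the Eades
  performance guarantee — at most `m/2 − n/6` removals — is preserved.
  Note the guarantee's domain: it holds for digraphs *without two-cycles*
  (a single two-cycle has `m = 2`, `n = 2` and already forces one
  removal, exceeding `2/2 − 2/6`); the validation suite therefore checks
  the bound on two-cycle-free connected instances and checks exact
  optimality exhaustively on all digraphs with up to four nodes.
* **PageRank** (`remove_cycles_pagerank`): power iteration with uniform
  teleport (damping 0.85, tolerance 1e-10, dangling mass redistributed
  uniformly), then removal of every hierarchy-violating edge. Because
  PageRank mass may flow either down or up a regulatory hierarchy
  depending on how a pathway encodes direction, both score orientations
  are evaluated and the cheaper one kept. A DAG input short-circuits: a
  DAG needs no removals even when its PageRank order is not topological.
* **Ensemble** (`remove_cycles_ensemble`): two hierarchies vote —
  TrueSkill posterior means (canonical priors μ₀ = 25, σ₀ = 25/3,
  β = σ₀/2, τ = σ₀/100; each edge `u → v` is a two-player match won by
  `v`; ten seeded-shuffle epochs) and a minimum-agony integer ranking
  (longest-path levels on the DFS DAG, refined by single-node moves; each
  node's incident agony is convex piecewise-linear in its rank, so the
  per-node minimiser is found by a scan). Edges are deleted one at a
  time — highest votes, then largest violation magnitude, then
  lexicographic — restricted to edges that still lie on a directed cycle
  (strongly-connected-component membership, re-checked after every
  deletion, so no unnecessary edge is ever removed).

The TrueSkill epoch count, PageRank damping, and the composition of the
ensemble's vote pool are configuration, fixed at the defaults above. The
agony minimiser is a local-search heuristic rather than the exact
primal-dual algorithm from the agony literature: what the ensemble needs
is a low-agony ranking that is exactly zero on DAGs, and the exhaustive
oracle in the test suite bounds the optimality gap (never above 1.5× the
optimum on small graphs, and equal to it in the large majority of random
instances). One consequence worth recording: on a two-cycle the minimal
possible agony is 2, not 1 — if the two ranks are equal both edges cost
one, and if they differ the down-edge costs at least two.

## Simulating expression data that fits a topology

The comparison needs expression data whose dependency structure follows
the *original* (possibly cyclic) network. The generator emulates what
SynTReN-style simulators do — Hill/Michaelis–Menten transfer kinetics,
external conditions applied to regulator-free genes, additive Gaussian
measurement noise — in seedable R, with these concrete choices:

* Each edge gets a Hill coefficient `n ∈ {1, …, 10}`, half-saturation
  `K ∈ [0.05, 1]`, and a role: activator for activating edges, repressor
  for inhibiting ones, sampled for unknown signs. Each gene gets a basal
  level `b ∈ [0.01, 0.2]`.
* A regulated gene relaxes to
  `clip01(b + (1 − b) · mean_e h_e(x_parent))`, where `h` is the Hill
  activation `x^n/(K^n + x^n)` or its repressor complement. The **mean**
  of edge-wise terms replaces SynTReN's combinatorial AND/OR input logic:
  it preserves monotone dependence on every regulator — which is what
  discrete BIC scoring can detect — with far fewer parameters. This is a
  deliberate divergence from the reference simulator.
* Cyclic networks have no evaluation order, so steady states are found by
  damped synchronous fixed-point iteration (`α = 0.5`, tolerance 1e-8,
  at most 500 sweeps) from 0.5; root genes are clamped at their sampled
  uniform(0, 1) inputs. Some parameterisations of feedback loops genuinely
  oscillate; non-converged samples are kept and flagged rather than
  silently dropped, and the pipeline warns when more than half a
  pathway's samples fail to converge.
* Gaussian noise (default sd 0.05) is added and values are clipped to
  \[0, 1\].

For multinomial scoring the continuous matrix is discretised per gene into
three equal-frequency levels (ties at a boundary go down; constant genes
become all zeros). Three quantile levels is the conventional preparation
of expression data for discrete Bayesian-network scoring and is exposed as
a parameter.

What the generator does *not* emulate: time courses, SynTReN's sampling of
subnetworks from real source organisms, and microarray-specific noise
models. Passing tests therefore demonstrate correctness of the machinery
and qualitative behaviour on topology-faithful synthetic data — not
performance on real expression data.

## BIC scoring and the random-DAG null

`local_bic()` is the decomposable multinomial BIC in the higher-is-better
convention: `Σ_jk N_jk log(N_jk/N_j) − (log N)/2 · q·(r − 1)` with natural
logs, states and parent configurations counted from the observed data
(quantile binning makes all levels occur by construction; a gene constant
in the data degenerates to `r = 1` and contributes exactly zero rather
than crashing). `bic_score()` sums local terms over the DAG, so changing
one gene's parent set changes exactly one term — asserted exactly in the
tests.

The null model is size-matched: for a DAG with `n` nodes and
`m` edges, `sample_random_dag()` draws a uniformly random gene permutation
and then `m` distinct forward pairs of it. This sampler is not uniform
over all DAGs, but it covers the full support (verified against exhaustive
enumeration at small size), is trivially seedable, and honours the only
stated constraint — matched node and edge counts. Ranks among the four
methods are dense descending ranks with ties sharing the better rank;
"randoms beating" counts are strictly-greater comparisons, so ties favour
the method DAG. Both tie rules are documented here because the source
design leaves them open.

A practical boundary worth knowing: with 3-level data and `N` samples, a
gene with `p` parents can gain at most `N log 3` nats of likelihood while
paying `(log N)/2 · 2 · 3^p`-ish of penalty, so nodes with five or more
parents are penalised beyond any possible gain at a few hundred samples.
The simulation-study fixture generator (`random_regulatory_dag()`)
therefore draws DAGs with in-degree capped at 3 and about 1.3 edges per
gene — the in-degree regime of the transcriptional networks SynTReN-style
simulators subsample — while the *null* DAGs remain unconstrained, since the null is defined
only by matched node and edge counts.

## The pipeline and its validation scale

`run_pathway()` chains the stages for one KGML file: parse → flatten →
collapse → (skip if fewer than 6 non-isolated genes: below that, a
DAG-fitness comparison is meaningless) → four DAGs → simulate → discretise → score each DAG and
its matched random DAGs → ranks. `run_benchmark()` maps this over a
directory and emits the per-pathway table, the per-method summary (the
four panels of the comparison: mean edges removed, mean removal rank, mean
score rank among methods, mean randoms beating) and a manifest with every
seed. All per-pathway seeds derive deterministically from the master seed,
so two runs with one configuration are byte-identical — asserted
file-by-file in the tests.

The validation suite runs at desk scale: 500 random mixed graphs (≤ 12
nodes) against the collapse oracle; 500 random cyclic networks (5–40
nodes) for the partition/acyclicity contract; exhaustive enumeration of
all ≤ 4-node digraphs for MFAS optimality; 200 random ≤ 5-node instances
against the exhaustive agony oracle; 100 cyclic fixtures (10–40 nodes,
1.2–2.0 edges per node) for the qualitative finding that the ensemble
needs the fewest removals; and 10 simulation seeds for the random-DAG
null. The default `n_random_dags` is 1000;
tests and the acceptance script run 20–200.

## Known limitations

* KGML reaction elements are associated with their catalysing entries via
  the entry `reaction` attribute (with the reaction id as fallback); maps
  using other association conventions would need their reactions curated.
* The agony ranking and the MFAS sequence are local-search heuristics:
  low, not provably minimal, on large graphs.
* The simulator's mean-combination transfer function cannot express
  XOR-like combinatorial regulation; dependencies it generates are
  monotone in each parent.
* Indirect-edge signs are conservative (`unknown` under any route
  ambiguity), so sign-sensitive consumers see fewer signed edges than a
  per-path analysis might recover.
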