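---
title: "netpharm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

This vignette records the scientific model the package implements, the
numerical and design choices that were genuinely open, and what the
synthetic-data world does and does not establish. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## The weighted disease gene network

Inputs are an undirected protein–protein interaction edge list and a
pathogenetic gene table carrying, per gene, the number of supporting
publications (a DisGeNET-style evidence count). Graphs are simplified on
load: self-loops dropped, duplicate edges (in either orientation)
collapsed. Evidence counts become node weights; genes in the evidence
table that do not map onto the network are reported and excluded rather
than added as isolated nodes — curated disease lists routinely contain
genes absent from any interaction screen, and an isolated node would
distort every distance-based statistic downstream.

Two "average degree" conventions circulate for dense PPI networks: the
conventional mean degree 2E/N and the plain edge-to-node ratio E/N. Both
are computed and reported (`mean_degree`, `edge_node_ratio`), because
published figures are sometimes the ratio: for a network of 949 nodes and
42,716 edges the ratio is 45.01 while the mean degree is 90.02. Naming
the ratio honestly, instead of calling it an average degree, keeps the
summary reproducible without mislabelling a standard quantity.

The disease–target network is the induced subgraph of the PPI on the
union of pathogenetic genes and component targets, with each node
annotated `disease`, `target` or `both` (the essential common targets).

## Node importance and the functional response space

For a node $s$,

$$\mathrm{Nim}(s) \;=\; \Bigl[\sum_{v \ne s \ne t}
\frac{\sigma_{vt}(s)}{\sigma_{vt}}\Bigr]
\times \sum_{x \ne s} \frac{1}{d(s,x)^2},$$

where $\sigma_{vt}$ counts shortest paths between $v$ and $t$,
$\sigma_{vt}(s)$ those passing through $s$, and $d$ is the unweighted
shortest-path distance. Numerical conventions, each pinned by a test:

- **Betweenness** is the raw (unnormalized) sum over unordered pairs with
  endpoints excluded. No normalization constant is applied because
  selection depends only on the ranking; ordered-pair summation would
  scale every score by 2 without reordering anything.
- **The proximity exponent** applies to the distance,
  $\sum 1/d(s,x)^2$, not to the sum. The alternative reading
  $(\sum 1/d)^2$ is available via `proximity = "square_of_sum"`; the
  default is pinned by tests.
- **Disconnected pairs** contribute nothing: pairs with no connecting
  path are skipped in the betweenness sum and $1/d = 0$ at infinite
  distance in the proximity sum. An isolated node scores 0 on both
  factors.
- **Node evidence weights** are carried on the graph but do not enter
  the importance formula, which is purely topological.

Nodes are ranked ascending by score with ties broken lexicographically by
node id, making the ranking — and everything downstream — deterministic.
The *functional response space* keeps the upper half of the ranking: the
top $(|V|+1)/2$ nodes for odd $|V|$, the top $|V|/2$ for even. This
median rule is the default because it forces an exact cardinality (918
of 1,836, say) regardless of the score distribution; a mean-threshold
rule (`rule = "mean"`, keep nodes strictly above the average score) is
exposed for comparison, but on heavy-tailed importance distributions the
mean sits far above the median and retains only the hub elite. Ties at
the cut are resolved by the same id ordering and flagged
(`tie_at_cut`), so the cardinality law holds even on degenerate score
vectors. Degree, closeness (with unreachable vertices scored 0) and
local clustering coefficient (isolates scored 0) feed the same selection
rule as baselines.

At the scale this package targets (~2,000 nodes) exact betweenness is
subsecond in igraph; no sampling or approximation is used. A brute-force
plain-R path-counting oracle verifies both factors to 1e-9 on all
shipped graphs of ≤ 12 nodes.

## Greedy contribution-ratio selection (KFCG)

Classical greedy maximum coverage over the effective-protein set: at each
step pick the component whose targets add the most uncovered effective
proteins; stop at the first step where cumulative coverage
$W = |\text{covered}|/|\text{effective}|$ reaches the threshold
(default 0.90) or when no component adds coverage (reported via
`threshold_reached = FALSE`, not an error). Choices worth recording:

- The coverage denominator is the effective-protein set, not the target
  universe; targets outside it contribute nothing. This is what makes
  "cover 90% of effective proteins" well defined.
- Tie-breaking is (1) larger marginal gain, (2) larger total target-set
  size, (3) lexicographic id — deterministic output, and the middle rule
  mirrors the convention of preferring the component with the larger
  overall target repertoire.
- Zero-gain components are never selected, so the coverage trace is
  strictly increasing and the selection is minimal in the greedy sense.
  Tests assert the classical $(1 + \ln |E|)$ approximation bound against
  exhaustively enumerated optima on small instances.

## Potential effect score

On the tripartite component–target–pathway graph (components joined to
their targets, targets to the pathways containing them; pathway genes
that are nobody's target are not added, and pathways left empty are
dropped),

$$\mathrm{PES}(k) = \Sigma(k_n) \times \Bigl[\frac{|V(k_p)|}{|V|}
\times \sum_{p} \frac{\Delta_k + 1 - \mathrm{dist}(k,p)}{\Delta_k}
\Bigr]^2 .$$

Interpretive decisions, since the published notation admits several
readings:

- $\Sigma(k_n)$ is the **sum of the degrees of the component's direct
  neighbours** — the "control" a component exerts scales with how
  connected its targets are, not merely with how many it has. The weaker
  reading (the component's own degree) is a special case and contradicts
  that intent.
- $|V(k_p)|$ is the number of nodes **reachable** from the component
  (excluding itself), over the total node count $|V|$.
- The proximity sum runs over **reachable pathways**, with
  $\Delta_k$ the maximum distance from $k$ to any reachable pathway;
  each pathway contributes $(\Delta_k + 1 - d)/\Delta_k$, a
  radiality-style weight that is 1 only when every pathway sits at the
  minimum possible distance. Unreachable pathways contribute 0
  (distance treated as infinite across components).
- Distances are unweighted hop counts; a component reaches its own
  pathway at distance 2 (component → target → pathway), so
  $\Delta_k \ge 2 \ge 1$ whenever any pathway is reachable and the
  denominator can never be zero. A component with no targets, or whose
  targets hit no pathway, scores exactly 0.

Scores are min–max normalized, $(x - \min)/(\max - \min)$: the maximum
maps to exactly 1.00 and the minimum to exactly 0.00 whenever the scores
are not all equal. The all-equal case maps everything to 0 — an arbitrary
but documented convention that realistic data never triggers.

## ADME screening

A component passes iff OB ≥ 30 (inclusive), Caco-2 > −0.4 (strict) and
DL ≥ 0.18 (inclusive); the asymmetric boundary semantics are deliberate
and pinned by a boundary-value test. Records missing any property fail
closed with reason `"missing"` — absence of evidence cannot pass a
screen — which is exactly how literature-curated components (no database
ADME predictions) are routed through `merge_literature()` instead.
Identity is the component id: the same molecule in several herbs is one
record, and conflicting property values for one id are an error rather
than a silent overwrite.

## Enrichment and validation

Over-representation uses the hypergeometric upper tail
$P[X \ge k]$ with the collection's full gene universe as background (the
standard default when no background is stated; the universe can be set
explicitly). Raw p < 0.01 defines significance by default, with
Benjamini–Hochberg behind `correct = "BH"`; the raw-p default mirrors
common practice in pathway screens of this kind and is the documented
convention, not a recommendation. Coverage of a reference term set is
$100 \cdot |\text{shared}|/|\text{reference}|$ rounded to 2 decimals,
with matching by term id. The three FRS validation indicators are the
gene-level coverage of the UET set and the term-level coverages for each
supplied collection.

## Dose-to-brain estimation

The estimation chain is deliberately naive and implemented literally:
100% extraction and absorption, linear (non-allometric) scaling from the
rodent anchor, 70 kg body weight, and brain tissue density 1 g/mL so
that ng/g divided by g/mol (≡ ng/nmol) reads directly as nmol/g ≡ nM.
The density assumption is required to express the result as a molarity
and is the only step not forced by arithmetic. Rounding is half-even to
2 decimals at the reporting stage only; intermediates keep full
precision, and the nM ↔ µM conversion is exact before rounding. One
shipped anchor (vanillic acid) derives from an injection study rather
than oral dosing; the config records the route so the caveat travels
with the number.

## The synthetic world

The generators produce every input the pipeline needs, with the
statistical structure the analysis assumes. Stated parameter choices:

- **Network**: preferential attachment (`pa_m` edges per node), which is
  connected and simple by construction and heavy-tailed in degree — the
  properties the hub-dominance and FRS assertions need. The paper-scale
  preset uses 1,836 genes at `pa_m = 14` (~25.6k edges, matching the
  scale of a published 1,836-node / 25,383-edge disease–target network).
- **Evidence counts**: $1 + \mathrm{Geom}(0.2)$ — every gene has at
  least one report and roughly 3% exceed 15, echoing curated disease
  lists where only a small minority of genes are heavily studied.
- **Targets**: per-component set sizes are log-normal
  (heavy-tailed; a few components have very many targets), and target
  identity is sampled degree-proportionally when the network is
  supplied, emulating the well-documented hub bias of real drug
  targets. Two construction guarantees make the pipeline feasible by
  design and are asserted post-generation: every non-disease gene is
  someone's target (so the merged network spans the full universe), and
  the union of active components' targets reaches ≥ 97% of all genes
  (so 90% coverage of any upper-half selection is achievable).
- **Pathways**: 60% of each set is drawn from the disease–target overlap
  pool, the rest from a genome-scale background universe of twice the
  network size. The background matters: when the universe equals the
  network, a query holding half of it can never be significantly
  enriched and every term-level metric degenerates.

What a green test does and does not establish: the synthetic world
reproduces *structural* behaviour — selection cardinalities, coverage
feasibility, normalization extremes, determinism — but not the biology.
Real PPI networks have community structure, correlated annotations and
ascertainment biases that preferential attachment does not model, so
agreement here says the algorithms are implemented as specified, not
that the method's biological claims transfer. In particular, on
preferential-attachment surrogates the importance ranking and the plain
degree ranking are strongly correlated, so the importance-vs-degree
coverage comparison is run on a fixed shipped fixture (paper-scale
preset, seed 2) where the ordering is strict; across arbitrary seeds the
two selectors differ only by noise. Reproducing the published coverage
percentages (99.10 / 97.30 / 80.43), the identity of the real
56-component group or the full published score ranking would require the
study's proprietary component–target data and live database access, and
is out of scope by design.

## Reproducibility

All generators and the pipeline are pure functions of (inputs, config,
seed): reruns are byte-identical, and the pipeline writes a manifest
with input MD5 checksums, parameters and the package version. The
acceptance script recomputes the headline numbers from scratch at every
invocation — nothing is cached or hard-coded.
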