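---
title: "Prioritizing disease genes by seed-pair shortest paths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes by seed-pair shortest paths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedpath)
```

## The model

`seedpath` implements a guilt-by-association method for discovering
novel disease genes from a protein–protein interaction (PPI) network
and a curated set of known disease genes (the *seeds*). The biological
premise is that interacting proteins tend to share function, so genes
that sit *between* known disease genes in the interaction network —
on the strongest chains of interaction evidence connecting them — are
good candidates for involvement in the same disease.

The method has four stages.

**1. Confidence-weighted graph.** The input is an interaction table in
the STRING links dialect: rows of `protein1 protein2 combined_score`,
where the combined score $Q(p_1, p_2)$ is an integer in $[150, 999]$
quantifying the confidence that the two proteins interact. The graph
takes every protein appearing in at least one interaction as a node,
and each unordered protein pair as one undirected edge with weight

$$W(v_1, v_2) = 1000 - Q(p_1, p_2),$$

so weights lie in $[1, 850]$ and high-confidence interactions are
*short* edges. A shortest path under this weighting is the chain of
interactions with the strongest cumulative evidence. Because STRING
files list each interaction in both orientations, both orientations
are parsed and merged to one edge at graph build; if the two
orientations ever disagree, the maximum score (minimum weight) wins —
conservative toward the stronger evidence.

**2. Seed-pair shortest paths.** For every unordered pair of seed
genes present in the graph, Dijkstra's algorithm finds a shortest
path. Seeds absent from the network are dropped (and counted);
seed pairs in different connected components are skipped (and
counted).

**3. Path betweenness.** Every gene is scored by the number of
seed-pair shortest paths on which it appears as an *inner* node (an
endpoint does not count for its own pair). Genes with positive
betweenness, minus the seeds themselves, are the *candidates*. Note
that a seed can accumulate betweenness by sitting inside other pairs'
paths; it is removed only at candidate selection.

This statistic is deliberately **not** classical betweenness
centrality: there is no normalization, no fractional split across
tied shortest paths, and only seed pairs — not all node pairs —
contribute. It is a raw count over at most $\binom{k}{2}$ paths for
$k$ seeds, and its magnitude depends on the seed set, which is what
makes the permutation null below meaningful.

**4. Permutation FDR.** High betweenness can be an artifact of a
gene's position in the network (hubs lie on many paths regardless of
which seeds are chosen). To filter such false positives, $N$ random
node sets $G_1, \dots, G_N$ of the same size as the seed set are drawn
uniformly without replacement from all graph nodes, the betweenness of
each candidate is recomputed on each $G_i$, and the candidate's score
is

$$\mathrm{FDR}(p) = \frac{1}{N} \sum_{i=1}^{N} \delta_i, \qquad
\delta_i = \mathbf{1}\{b_i(p) > b(p)\},$$

the fraction of random seed sets under which the candidate's
betweenness *strictly* exceeds its observed value. Candidates with
$\mathrm{FDR} < 0.05$ (strict) are reported as significant. Although
called an FDR here (following the field's usage for this quantity), it
is formally a per-gene empirical exceedance probability, not a
Benjamini–Hochberg-style rate; the column name is kept for continuity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_permutations` | 1000 | random seed sets for the null; FDR resolution is `1/n_permutations` |
| `fdr_threshold` | 0.05 | strict significance cutoff on the permutation FDR |
| `min_score` | 150 | parse-time floor on combined scores (150 is the floor of the score range itself; raising it prunes weak edges) |
| `mode` | `"canonical"` | tie handling for multiple shortest paths (below) |
| `pseudo_count` | `FALSE` | switch to the `(r+1)/(n+1)` exceedance estimator |
| `rng_seed` | 1 | root seed for the permutation draw |

The defaults reproduce the method as defined: 1000 permutations, a
strict 0.05 cutoff, raw exceedance fractions, and one canonical path
per seed pair.

## Numerical and algorithmic choices

**Tie handling.** A weighted graph can contain several equally short
paths between a seed pair. The default *canonical* mode picks exactly
one: walking back from the target, the predecessor of a node $v$ is
the lexicographically smallest neighbour $u$ satisfying
$\mathrm{dist}(u) + W(u, v) = \mathrm{dist}(v)$. This definition
depends only on the final distances, so it is independent of
relaxation order, reproducible across platforms, and cheap. The
alternative `mode = "all"` instead credits a pair to *every* gene
lying on *any* of its shortest paths (a node $v$ is on some shortest
$s$–$t$ path iff $d_s(v) + d_t(v) = d_s(t)$); each pair then counts a
gene at most once. Canonical mode is the default because the method is
defined in terms of *the* shortest path per pair, and integer weights
over a sparse score distribution make heavy ties uncommon on real
STRING-scale data; both modes are exposed because the choice is
genuinely underdetermined.

**Strict exceedance.** Ties between permuted and observed betweenness
contribute nothing to the FDR ($\delta_i = 0$ at equality), which
favors significance. This differs from the common
$(r+1)/(n+1)$ permutation-p convention, which is available via
`pseudo_count = TRUE` but off by default.

**Determinism.** The permutation draw uses one root seed that expands
into one sub-seed per permutation, so (i) any single permutation can
be reproduced in isolation, (ii) results are independent of the order
in which permutations are evaluated — the contract a parallel
implementation must satisfy — and (iii) a rerun with the same inputs
and root seed reproduces the output report byte for byte. Seed-pair
enumeration is over sorted seed identifiers; candidate tables break
ties by gene identifier; report FDRs are printed in plain decimal
notation.

**Exactness.** Edge weights are integers in $[1, 850]$, so path sums
are small integers and all distance comparisons (including the
canonical-predecessor equality test) are exact in double arithmetic.
Dijkstra runs in compiled code over a compressed adjacency; a
STRING-scale graph (tens of thousands of nodes, around a million
edges, under a hundred seeds) is tractable with exact single-source
runs, one per seed.

**Degenerate inputs.** Self-loops are dropped at parse time;
duplicate rows merge at graph build; an empty interaction file is a
fatal "empty network" error; a seed list resolving to fewer than two
in-graph genes is a fatal error distinct from an I/O failure (the
command-line wrapper maps these to distinct exit codes).

## The synthetic generators

Real STRING snapshots are large, versioned, and unnecessary for
validating the algorithmic claims, so all test inputs are generated:

* `figure1_fixture()` pins a published worked example: a seven-node
  graph where the unique cheapest route between the two seeds `a` and
  `d` is `a–e–f–g–d`, the `a`–`e` edge has weight 20 (combined score
  $1000 - 20 = 980$), and every alternative route is strictly
  heavier. The pipeline must report exactly `e`, `f`, `g`, each with
  betweenness 1.
* `random_network()` draws Erdős–Rényi graphs with uniform scores —
  the null landscape for calibration experiments and the substrate
  for oracle comparisons.
* `planted_module_network()` wires a known answer: seeds attach
  round-robin to a clique of connector genes by score-980 edges, on a
  denser low-score background (scores 300–400). Module genes tie into
  the background only through weakest-score edges (150, weight 850),
  so a background detour between two seeds costs at least 1700 versus
  at most 60 through the module, and conversely no background pair
  ever saves by cutting through the module. Ground truth follows by
  construction: every connector carries at least one seed-pair path
  and no background gene carries any.

What these generators deliberately do **not** emulate: the heavy-tailed
degree distribution, evidence-channel correlations, and score
distribution of real STRING data. Passing tests therefore demonstrate
algorithmic correctness (distances, counts, null machinery,
reproducibility) and recovery under a controlled signal, not
biological performance on real networks.

## Validation strategy and problem sizes

The test suite checks every stage against independent oracles:
exhaustive simple-path enumeration on graphs of up to 8 nodes (100
random graphs) for distances, canonical paths and betweenness; an
independent graph library for distances on a 40-node graph; binomial
bounds on permutation-set inclusion frequencies; hand-counted
exceedance examples for the FDR; and byte-identity for reproducibility.
Calibration and recovery experiments run at deliberately modest sizes
chosen to keep the full suite fast while leaving no stage untested: a
200-node, edge-probability 0.1 network with 15-gene null seed sets (20
replicates × 200 permutations) for calibration, and the default
49-node planted-module fixture with 200 permutations for recovery.

## Known limitations

* **The permutation FDR is anti-conservative for rarely-selected
  genes.** Because the score is computed only for genes with observed
  betweenness > 0 and uses a strict exceedance count, a gene that is
  rarely an inner node under the null almost automatically receives a
  near-zero FDR on the occasions it *is* selected: its null
  betweenness distribution is mostly zeros, so few permutations can
  strictly exceed even a small observed count. Empirically (null seed
  sets on the 200-node calibration network), candidates that appear in
  ≥ 75% of null replicates show a sub-threshold fraction near the
  nominal 0.05, while candidates appearing in < 25% of replicates show
  roughly half of their FDRs below 0.05. The pooled fraction of
  sub-threshold FDRs under the null is therefore well above 0.05
  (≈ 0.14–0.16 in our experiments), i.e. the statistic as defined does
  not behave like a uniform p-value across candidates. Users should
  treat significance of low-betweenness, rarely-central candidates
  with caution; the `pseudo_count` option tempers but does not remove
  this effect, since it stems from conditioning on candidacy rather
  than from the estimator alone.
* The "FDR" is a per-gene empirical exceedance probability; it is not
  corrected for testing many candidates.
* Canonical-path counting under heavy weight ties can under-credit
  genes that lie only on non-canonical tied paths; `mode = "all"` is
  the remedy when tie density is a concern.
* Betweenness is blind to path multiplicity off the shortest routes:
  a gene on many *near*-shortest chains scores zero.

## A worked run

```{r worked}
fx <- figure1_fixture()
fit <- seedpath(fx$graph, fx$seeds, n_permutations = 200, rng_seed = 1)
fit
fit$candidates
```

```{r planted}
pm <- planted_module_network(rng_seed = 42)
fit2 <- seedpath(pm$graph, pm$seeds, n_permutations = 200, rng_seed = 42)
summary(fit2)
```
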