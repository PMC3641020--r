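---
title: "Seed-gene PPI network topology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene PPI network topology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The model

`seednet` treats a disease as a perturbation distributed over a
protein–protein interaction (PPI) network rather than a property of single
genes. Its input is a panel of candidate disease genes (the *seeds*; the
package ships the 69-gene essential-hypertension panel as
`inst/extdata/eh_seed_genes.tsv`) and a table of scored pairwise
interactions in the STRING export style. The object of study is the
**extended network**: seeds, their direct interaction partners at a
confidence threshold, and *all* interactions among that node set. Keeping
the induced neighbour–neighbour edges matters — they create the alternative
routes that betweenness is supposed to measure.

All analysis runs on the **giant component**. Small detached components
(in the hypertension panel, the CYBA- and PSMA6-derived satellites) cannot
carry high betweenness and are reported but not analysed.

Three node measures drive everything downstream, all on the unweighted
graph — confidence scores act purely as an inclusion filter, never as edge
lengths, because an interaction either is or is not credible enough to use;
its score is not a distance:

* degree $k(v)$: the number of interaction partners;
* betweenness $BC(v) = \frac{2}{(N-1)(N-2)} \sum_{s \ne v \ne t}
  \sigma_{st}(v)/\sigma_{st}$, with $\sigma_{st}$ the number of distinct
  shortest $s$–$t$ paths and endpoints excluded. The pair normalization
  (the convention of the classic network-analysis tools, so a star centre
  scores exactly 1) is stated here prominently because raw and normalized
  betweenness differ by a constant that is easy to mistake for a
  discrepancy;
* closeness $CC(v) = (N-1)/\sum_u d(v,u)$.

Global statistics are $N$, $E$, $\langle k\rangle = 2E/N$, the diameter
(longest shortest path, integer steps) and the mean shortest path length
over unordered pairs. A note on $\langle k\rangle$: published network
tables sometimes carry an average degree inconsistent with their own
$N$ and $E$ (a 535-node, 2572-edge network has $\langle k\rangle = 9.61$,
not 7.61). The package always computes $2E/N$ and does not attempt to
reproduce such values.

## Backbone, key nodes, seed subnetwork

The **backbone** is the induced subgraph on the top 5% of giant-component
nodes by betweenness. The cutoff count is $m = \lceil 0.05\,N \rceil$
(5% of 535 is 26.75, hence 27), and boundary ties are *included* rather
than truncated: membership should not depend on how a sorting algorithm
happens to break an exact tie. A degree ranking one node longer than the
betweenness ranking at the same nominal fraction is the natural signature
of such a tie, so inclusion is also what published key-node tables imply.
Tie inflation is flagged on the result. Report *order* (as opposed to
membership) breaks ties deterministically by score descending then node
name.

Key nodes follow the four-way hub/bottleneck scheme: *hub* = top 5% by
degree, *bottleneck* = top 5% by betweenness, giving hub–bottleneck,
hub–nonbottleneck, nonhub–bottleneck and nonhub–nonbottleneck classes that
partition the node set.

The **seed subnetwork** is the induced subgraph on the union of the
vertices of *all* shortest paths between every pair of seeds. Membership
is decided by the exact criterion $d(s,v) + d(v,t) = d(s,t)$ — a node lies
on at least one shortest $s$–$t$ path if and only if that identity holds —
rather than by enumerating paths, which yields the identical node set at
$O(|S| \cdot N)$ memory with no combinatorial explosion. Explicit
predecessor-DAG enumeration is still available
(`enumerate_shortest_paths()`) with a per-pair path cap (default $10^5$)
that aborts loudly instead of silently sampling; the test suite uses
independent brute-force enumeration to confirm both routes agree. Two
further choices are deliberate: the subnetwork keeps *induced* edges among
its nodes, not only edges lying on collected paths (the subnetwork is a
network in its own right, and dropping induced edges would misstate its
density); and betweenness is recomputed *within* the subnetwork, since the
question it answers — who integrates the seed genes — is internal to it.
Because shortest paths are closed under taking prefixes, the subnetwork is
always connected and contains every seed present in the giant component.

## The seed-omission robustness protocol

A central protein claimed from one seed panel should not owe its position
to any single seed. The protocol rebuilds the extended network from
reduced seed sets:

* $k = 1$: every seed omitted once ($|S|$ networks);
* $k = 2$: the central gene paired with every other seed ($|S|-1$);
* $3 \le k \le k_\max$: the central gene plus a uniform draw of $k-1$
  others, `draws_per_k` independent draws per $k$ (duplicate draws are
  kept — the draws are defined as independent, and deduplication would
  break the fixed group sizes).

With 69 seeds, $k_\max = 7$ (about 10% of the panel) and 30 draws per
$k$: $69 + 68 + 5 \times 30 = 287$ test networks. Omitted genes may
re-enter as neighbours of remaining seeds; this is essential, not a leak —
it is how a non-seed protein can demonstrate that the network, not the
panel, makes it central.

Each test network reports its largest-BC node and its **backbone
accuracy**: the fraction of its top-$M$ BC nodes that belong to the
reference backbone, with $M$ frozen at the reference backbone's size (27
in the reference study), *not* recomputed as 5% of each test network —
the comparison must be against a fixed reference set. If a test network's
giant component is smaller than $M$ the ratio is taken over the available
nodes, with a warning. Argmax ties are broken lexicographically and would
be visible in the detail table; on real-valued BC they essentially never
occur, but determinism must not depend on that.

The summary aggregates per-$k$ groups: frequency of each node as the
largest-BC node, mean accuracy per group, and an overall accuracy defined
as the **unweighted mean of the per-group means**. The unweighted mean is
the deliberate primary definition — each omission depth is one experimental
condition, and the heavily populated $k = 1, 2$ groups should not dominate
the answer — but because the network-weighted mean is the other defensible
convention, it is also computed and labelled
(`overall_accuracy_weighted`). On the published hypertension group values
the two differ (≈0.803 vs ≈0.821), so the choice is visible, not cosmetic.

## The synthetic interactome

The generator produces inputs with provable ground truth, emulating the
structure of a STRING-derived disease interactome:

* a scale-free background (preferential attachment), since real PPI
  networks concentrate edges on a few hubs;
* `n_modules` cliques attached to the rest of the graph *only* through a
  designated **bridge** node, which is therefore a cut vertex: every
  shortest path between a module node and anything else, and between two
  modules, traverses it. A verification pass asserts the cut property on
  the above-threshold graph at generation time;
* the bridge additionally attached to `n_anchors` background nodes chosen
  at spread *moderate* degree ranks (25%–60% of the degree order). Both
  choices are load-bearing and came out of an explicit design analysis:
  anchoring the bridge to the top hubs hands the module traffic to a node
  that already owns the background traffic, which can then outrank the
  bridge; and with too few anchors the module traffic converges back onto
  a hub one step downstream. Many moderate anchors split the module
  traffic while the bridge carries all of it, and let the bridge shortcut
  background geodesics away from competitor hubs. With the default
  2 modules × 25 nodes and 15 anchors at the 500-node default scale (2 ×
  12 and 8 anchors at the ~150-node test scale), the bridge is the
  betweenness maximum across generator seeds;
* `n_satellites` detached two-node components (the CYBA/PSMA6 analogue),
  each contributing one seed;
* integer confidence scores with a fixed 20% of edges below the 400
  threshold, so score filtering is always exercised; structural edges
  (module, bridge-incident, satellite, and a background spanning tree)
  always score above threshold so filtering never severs the designed
  giant region;
* seeds sampled so that two anchors and two members of every module are
  always seeds (hence no single omission can disconnect the bridge), the
  bridge itself is *not* a seed by default, and — when the interaction
  table is supplied — a deterministic repair pass replaces any background
  seed whose neighbourhood fails to join the giant component of the
  extended network, so the designed membership is exact.

What the generator does **not** emulate: biological interactome growth
(duplication–divergence), realistic score calibration, node-identifier
semantics, or the size of the real STRING network. Passing the recovery
tests therefore shows the *pipeline* is correct — construction, filtering,
centralities, backbone, protocol — not that any particular biological
network has a bridge-like protein.

## Numerical and degenerate-input choices

* Symbols are upper-cased opaque tokens; an optional alias table remaps
  interaction identifiers to seed symbols before construction.
* Interaction cleaning: self-rows dropped; duplicate and reversed rows
  collapsed keeping the maximum score (idempotent). Scores are canonical
  on 0–1000; 0–1 inputs are rescaled; a two-column dialect scores at the
  maximum.
* The confidence threshold default is 400 ("medium confidence" in the
  combined-score convention); it is configurable and recorded in the run
  manifest, since published analyses often leave it unstated.
* Seeds absent from the filtered table are dropped with a warning by
  default, or kept as isolated flagged nodes (`keep_missing_seeds`).
* Centralities refuse disconnected input (no silent harmonic fallback) and
  direct the caller to component extraction; betweenness is defined as 0
  for networks with fewer than 3 nodes.
* Equal-sized components: the giant is the one with the lexicographically
  smallest member, so decomposition is deterministic.
* Pajek output is the undirected dialect (`*Vertices N`, 1-based ids,
  quoted labels, `*Edges`); `*Arcs` input is rejected with a clear message.
* Report floats are written at 5 decimals.
* Every randomized stage takes a named integer seed; identical seeds give
  byte-identical plans, generated data and report tables.

## Problem sizes used in the shipped checks

The test suite and acceptance script exercise oracle comparisons on graphs
of up to 10 nodes (where explicit all-path enumeration is exact and
cheap), synthetic studies of about 150 interactome nodes with 20 seeds,
and protocol/aggregation identities at the reference panel's actual sizes
(69 seeds, 535-node giant, 287 test networks). These sizes were chosen so
that every assertion is checkable against enumeration or construction
guarantees; the pipeline itself has no size-dependent logic and runs
unchanged on full-scale interactomes.

## Known limitations

* Betweenness is exact, not approximate; for interactomes of $10^5$ nodes
  an approximate or parallel implementation would be needed.
* The pipeline operates on symbols; it does not resolve protein isoforms
  or identifier namespaces beyond the optional alias table.
* The robustness protocol perturbs the seed panel only; edge-level
  perturbations (interaction noise) are out of scope.
* Published reference values that depend on a specific historical
  interactome snapshot (giant-component size, individual centrality
  values) cannot be recomputed from a seed list alone and are treated as
  documentation, not as targets.
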