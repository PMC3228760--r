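---
title: "Single-copy ortholog discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-copy ortholog discovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scortho)
```

## The problem

A gene is *single copy* since an ancestor when no duplication and no loss
has occurred in any descendant lineage. Copy-count scans over orthologous
groups find such genes only when the whole group is single copy; any family
touched by one ancient duplication is discarded, even if one of its paralog
clades has been perfectly single copy ever since. `scortho` recovers those
clades by reconciling each family's gene tree with a guide species tree and
scanning the reconciliation for clean sub-trees.

## Reconciliation model

Given a rooted binary species tree $S$ and a rooted gene tree $G$ whose
leaves are mapped to species, the LCA mapping assigns to every gene node the
lowest species node that could have contained it:
$M(\ell) = \text{species}(\ell)$ for leaves and
$M(v) = \mathrm{lca}_S\{M(c)\}$ over the children $c$ of $v$. Under
duplication–loss parsimony this mapping attains the minimum event count; an
internal node is a **duplication** iff it maps to the same species node as
one of its children. Losses are charged per gene-tree edge $(v, c)$ from the
species path length $d = d_S(M(v), M(c))$: $d - 1$ when $v$ is a speciation
(each species branching passed without a sister lineage is one loss) and $d$
when $v$ is a duplication (the extra copy also misses the branching at
$M(v)$ itself). Costs are unweighted (duplication = loss = 1), matching the
"fewest duplications and losses" criterion; the test suite verifies the
implementation against a brute-force minimum over all event-consistent
embeddings, exhaustively on small trees.

Two consequences of this classical convention worth knowing:

* Reconciliation is relative to the image of the gene-tree root. A family
  that lacks an entire basal clade maps its root *below* the species root
  and is not charged for the absence; correspondingly, sub-tree calls
  require the sub-tree root to map *exactly* to the focal node, so families
  missing whole clades are never called at that level.
* A gene tree congruent with $S$ with one gene per species has cost 0, and
  grafting a species-specific duplicate raises the cost by exactly one
  duplication.

## Rooting

Gene trees are inferred unrooted. Every edge of the unrooted tree is tried
as a root position (2n−3 for a binary tree), each rooting is reconciled, and
the minimum-cost one is used. All co-optimal root edges are reported; the
representative is the edge whose root bipartition key (sorted leaf labels,
lexicographically smaller side first) is smallest, which makes results
deterministic without hiding ambiguity. In the pipeline, sub-tree calls are
taken from **every** co-optimal rooting and unioned during pooling, since
there is no principled reason to prefer one tied rooting's calls.

## Support collapse and soft polytomies

Branches with bootstrap support strictly below the threshold (default 80,
with the boundary kept: support exactly 80 is retained) are contracted into
multifurcations before reconciliation. A branch carrying *no* support value
is treated as resolved and kept: only branches that demonstrably fail the
criterion are removed. This is a deliberate reading of an underspecified
convention; the alternative (collapsing unvalued branches) would destroy
fully resolved input trees that simply lack annotations.

Multifurcations are *soft*: they encode uncertainty, not simultaneous
divergence, and must not be charged as conflict. Each polytomy is refined to
a binary resolution of provably minimal duplication+loss cost by a dynamic
programme over the species subtree spanned by the polytomy's children.
$f(s, k)$ is the minimal cost of accommodating all children mapping at or
below species node $s$ given $k$ gene lineages crossing into $s$: lineages
may duplicate at $s$ (cost 1 each), terminate on children mapped at $s$,
speciate into both species children, or continue one-sided (cost 1 loss per
branching passed). For fixed child lineage counts the cost is linear and
decreasing in the number of speciating pairs, so each cell takes the maximal
pairing; an optimal binary refinement is reconstructed by backtracking, with
created nodes flagged as inferred.

A simpler construction — group the polytomy's children by their mapping and
assemble the groups following the species topology — is *not* optimal:
for children $\{a_1{:}A, a_2{:}A, b_1{:}B, b_2{:}B\}$ under $(A,B)$ it pays
two within-species duplications, whereas a single duplication in the
ancestor followed by two clean speciation pairs costs 1. The DP finds the
latter; the test suite checks equality with the enumeration of all binary
resolutions (up to 945 for six children) across hundreds of random cases.

Refinements of distinct polytomies are independent: the mapping of a
polytomy's root is invariant under refinement, so local minima compose to
the global minimum.

## Single-copy sub-tree extraction

Within the best reconciliation, a sub-tree $T$ is called single copy since
focal node $F$ when:

1. $M(\mathrm{root}(T)) = F$;
2. every internal node of $T$ is a speciation, except duplications mapping
   to a species *tip* (a copy-number anomaly confined to one genome,
   typically an unannotated pseudogene);
3. every loss charged on an edge inside $T$ is of a single terminal taxon
   (typically an annotation gap);
4. the distinct taxa carrying such events number at most `budget`
   (default 1, mirroring the taxon-count tolerance); a duplication and a
   loss draw on the same budget — the tolerance is "one deviating genome",
   not one per event kind;
5. $T$ is maximal: no called sub-tree is nested in another.

Because speciation-only sub-trees embed injectively into the species tree,
conditions 1–3 already exclude sub-trees that topologically conflict with
the guide tree. The budget is applied per sub-tree, not per family; with a
larger genome panel a higher budget may be appropriate, which is why it is a
parameter rather than a constant.

The default budget of 1 deviating genome reflects two empirical
observations about curated genome sets: published genomes are incomplete
and unannotated pseudogenes masquerade as duplications, so a single
deviating genome is more often artefact than biology.

## Taxon-count baseline and classification

`taxon_count_call()` certifies a group when at most `tolerance` taxa of the
universe deviate from exactly one copy; categories are `exact`,
`one_duplication`, `one_loss` (and `mixed` for higher tolerances).
`classify_relationship()` labels copy-number vectors `one_to_one` /
`one_to_many` / `many_to_many` counting only taxa with two or more copies:
absent taxa do not demote a group from 1-to-1, because spanning the full
taxon set is a separate criterion enforced by the caller. Pooling across
guide trees deduplicates by exact (group, gene set); near-identical sets
differing by one tolerated event are kept apart for manual review rather
than silently merged.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `support_threshold` | 80 | % bootstrap | collapse branches below this |
| `tolerance` | 1 | genomes | taxon-count deviation allowance |
| `budget` | 1 | genomes | species-specific events per sub-tree |
| `dup_rate`, `loss_rate` | 0.2 | events / unit branch | simulator birth–death rates |
| `dropout_prob` | 0.08 | probability / gene | simulator annotation dropout |

The simulator's species tree is scaled to unit root height, so rates are
per total tree depth; 0.2 yields families where a minority carry events,
matching the regime where most groups are candidate single-copy markers.
The dropout default of 0.08 mirrors the ~8% of genes observed missing per
genome in curated metazoan genome sets.

## What the simulator does and does not emulate

`simulate_family()` propagates one lineage from the species root; along
each branch of length $t$ every incoming copy gains $\mathrm{Pois}(\lambda
t)$ duplicates and each resulting copy survives with probability
$e^{-\mu t}$. Two documented simplifications: duplicates created on a
branch do not re-duplicate within that same branch, and losses are applied
as end-of-branch survival thinning rather than competing event times. Both
matter only at second order in the rates; the branching-process expectation
used by the tests accounts for lineage growth exactly.

The simulator emulates copy-number evolution and annotation dropout. It
does **not** emulate gene-tree estimation error: simulated gene trees are
correct by construction (supports, when present, are genuine). A green
recovery test therefore establishes that the pipeline's logic is right, not
that it is robust to phylogenetic reconstruction artefacts — on real data
the support-collapse step is the only defence against those, and the
strictness of the congruence conditions trades sensitivity for precision
exactly as a conservative caller should.

Truth labels are event-based: a family is flagged single copy iff its event
log is empty. A family whose duplication is exactly compensated by a loss
of the new copy can still pass a zero-tolerance taxon count; the benchmark
cross-check in the tests treats that case explicitly.

## Numerical and degenerate-input choices

* Rooting at an edge places the root at the edge midpoint when lengths
  exist (cosmetic: reconciliation ignores lengths); the edge's support is
  carried onto both root branches, which represent the same bipartition.
* Contracted branches discard their length (the `ape::di2multi`
  convention); promoted children keep theirs.
* Pruning that leaves a single leaf returns a degenerate one-tip tree
  flagged `degenerate`; pruning to an empty set is an error.
* Species trees must be rooted and fully binary; polytomous guides are
  rejected rather than silently resolved, since every loss count depends on
  the guide's branching structure.
* Ties among co-optimal rootings and within polytomy realisations are
  broken deterministically (bipartition key; input child order), so all
  outputs are reproducible byte for byte.
* Child order is preserved from input everywhere, but all comparisons in
  the package and its tests are order-insensitive (canonical-form based).

## Known limitations

* Only duplication and loss are modelled: no horizontal transfer,
  incomplete lineage sorting, or dated reconciliation. For intra-kingdom
  animal datasets this is the standard assumption set.
* The all-rootings sweep is quadratic in tree size (each rooting is
  reconciled independently); fine for family-sized trees (tens to a few
  hundred leaves), not tuned for trees with thousands of leaves.
* The rescue is deliberately conservative: sub-trees that differ from the
  guide tree through reconstruction artefacts are excluded even when the
  underlying family is single copy, reducing sensitivity in exchange for
  precision of the marker set.
* Assignment of query sequences to groups (for completeness reports) is
  upstream similarity-search territory and out of scope; `completeness()`
  consumes precomputed assignment tables.
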