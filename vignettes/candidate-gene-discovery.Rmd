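---
title: "Candidate gene discovery by bridging disease genes in PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate gene discovery by bridging disease genes in PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
library(dplyr)
```

## The problem

Monogenic disorders with many causal genes — inherited retinal dystrophies
such as retinitis pigmentosa (RP) are the motivating case — pose a
paradox: defects in any one of dozens of different genes produce the same
clinical picture. The disease-module view of network medicine resolves it by
positing that the causal genes occupy one connected neighborhood of the
protein interactome, so their products participate in a shared molecular
process. Two practical consequences follow, and this package operationalizes
both:

1. if a curated causal gene fails to interact with any other causal gene,
   the *gene that connects it* to the module — an intermediate, or bridge,
   gene — is itself a plausible, undiscovered causal gene
   (guilt-by-association);
2. interacting proteins tend to share a cellular compartment, so a sparse
   manual annotation of compartments can be extrapolated over the whole
   module from the interaction pattern alone.

The pipeline takes a disease gene list, a confidence-scored undirected PPI
edge table (the STRING protein-links flat file or any three-column TSV), an
optional identifier alias map, and an optional seed assignment of a few
genes to localization groups. It returns a connectivity classification of
the input genes, one selected bridge per disconnected gene, a localization
group for every gene, and an inter/intragroup connectivity matrix.

## Connectivity classification and bridge selection

Let $G = (V, E)$ be the simple undirected graph whose edges carry
confidences $c(u,v) \in [0,1]$, after discarding edges below a threshold
$\tau$ and merging duplicate rows by maximum confidence. For an input gene
set $S \subseteq V$:

* **direct** genes ("group A") have at least one edge to another member of
  $S$;
* the **main component** $M$ is the largest connected component of the
  subgraph induced on the direct genes (size ties go to the component
  containing the lexicographically smallest symbol);
* for each remaining gene $b$, the **bridge candidates** are the non-input
  neighbors $v \notin S$ of $b$ with at least one edge into $M$. The default
  score is the additive two-leg score
  $$s(v \mid b) = c(v, b) + \max_{u \in M} c(v, u),$$
  and the gene is **bridged** ("group B") by the top-scoring candidate, or
  **unbridgeable** ("group C") if no candidate exists. Selected candidates
  form the intermediate set ("group D").

Design choices where the procedure was genuinely open:

* **Score form.** Any monotone combination of the two legs a bridge must
  have is defensible; the additive form is the simplest and treats both
  legs symmetrically. `score_strategy` exposes two alternatives:
  `"all_links_sum"` (replaces the max by the sum over all main-component
  links, favoring hub intermediates) and `"min_leg"` (a bottleneck score).
  All three agree on the forced cases (a single candidate), which is the
  regime the recovery guarantees address.
* **One hop, to the main component.** Candidates are restricted to direct
  neighbors of the disconnected gene (no two-hop chains), and the second
  leg must reach the *largest* direct component rather than any direct
  gene: the aim is one connected module, and bridging into a minor
  fragment would not achieve it.
* **Sharing.** Two disconnected genes may select the same intermediate;
  since the point of pairing one intermediate per gene is to keep the
  augmented map minimal, sharing is a feature, not a conflict.
* **Tie-breaking.** Equal scores fall to more links into the main
  component, then to the lexicographically smaller symbol, making the
  selection a pure function of the input. Scores are rounded to nine
  decimals before comparison so that sums which are equal by construction
  are not separated by floating-point representation.

```{r classify-example}
net <- build_ppi_network(tibble::tibble(
  gene_a = c("A", "B", "C", "X", "M", "M"),
  gene_b = c("B", "C", "A", "M", "A", "B"),
  confidence = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.45)
))
cl <- select_intermediates(net, classify_connectivity(net, c("A", "B", "C", "X")))
tidy(cl)
```

## Localization by iterated PPI-count majority

Starting from seed genes with known compartments (for the retinal presets,
group 1 = retinal pigment epithelium, 2 = photoreceptor outer segment, 3 =
connecting cilium, 4 = nucleus), `assign_localization()` repeats rounds in
which every unassigned gene with at least one edge to an assigned gene
takes the group holding the plurality of those edges. Counts tie to the
greater sum of edge confidences.

Three procedural decisions deserve justification:

* **Batch-synchronous rounds.** All decisions in a round are made against
  the assignment frozen at round start. A sequential update would make the
  outcome depend on the arbitrary order in which genes are visited; the
  batch rule removes that dependence (a property the test suite checks by
  permuting the universe), at the cost of needing one extra round where a
  sequential scheme might finish earlier. The growing groups then allow
  genes skipped in early rounds to be revisited, which is why iteration —
  rather than a single pass — is essential.
* **Votes come from all assigned genes**, seeds and previously assigned
  alike, not from seeds only; the whole point of iterating is that the
  expanded groups carry information.
* **Residual ties and deadlock.** A gene tied on both count and confidence
  sum is deferred one round — the groups usually grow and break the tie
  naturally — and, if the tie persists, resolved to the lowest tied group
  index with a warning rather than left dangling. Genes with no edge to
  any assigned gene when a round makes no progress are reported as
  `unassigned`; the algorithm never invents a group for a gene with no
  supporting interaction. `max_iterations` (default 100) is a safety cap
  only; on connected inputs the loop terminates by progress exhaustion
  long before it.

Intermediates are then *placed*, not propagated: each inherits the group of
the disconnected gene it serves (`place_intermediates()`), since its sole
reason for membership is that partnership. An intermediate shared by
partners in different groups follows the lexicographically smallest partner
and warns. In the full protocol the propagation universe is the augmented
network (inputs plus intermediates), so a disconnected gene — whose only
link may be its bridge — is reachable: the bridge is assigned first through
its main-component links, the disconnected gene one round later, and the
placement rule finally overrides the bridge's label with its partner's.

The `connectivity_matrix()` counts each edge between assigned genes exactly
once under the unordered pair of endpoint groups. Whether edges incident to
intermediates belong in those totals is a judgement call, so both readings
are reported: `counts` includes them through the intermediates' inherited
groups, and `intermediate_links` separately tallies, per group, the edges
touching an intermediate.

## What the synthetic generator emulates

`synthetic_scenario()` draws a planted-partition network: four blocks dense
inside (`p_intra`) and sparse between (`p_inter`), the minimal model of the
compartment assumption the localization step relies on. On top of the
random background it plants, deterministically: a spanning cycle in each
block (so blocks are connected), a path through each block's disease genes
(so known disease genes are directly connected), one disease–disease edge
between consecutive blocks when `p_inter > 0` (so the disease module is a
single component), and, per isolated disease gene, a dedicated bridge wired
to the gene and to disease genes of block 1. Planted edges draw confidences
at or above the pipeline threshold; background edges may fall below it.
Isolated genes and their bridges are carried as block 1 in the ground
truth, which is where the pipeline's placement rule will put them.

The defaults mirror the RP study conditions at full scale — 159 disease
genes of which 10 are isolated, one bridge each, a 0.400 threshold, and
roughly 20% of the connected disease genes seeded — so a default run
exercises the protocol at the size it is meant for. The generator
deliberately does *not* reproduce two features of real interactomes:
scale-free degree distributions (blocks are Erdős–Rényi inside) and
STRING's evidence-channel structure (a single combined confidence is
drawn). Passing recovery tests on these scenarios therefore demonstrates
algorithmic correctness — that the implementation recovers planted
structure whenever the premises hold — not biological validity of any
particular bridge call on real data.

Test and acceptance runs use reduced problem sizes chosen to keep the
guarantees analytically forced while remaining quick: 15-gene blocks for
pipeline-closure fixtures, 12-gene blocks across 100 replicates for bridge
recovery (recovery is exact there because each isolated gene has exactly
one valid candidate — uniqueness, not luck), 30-gene blocks for label
propagation, and graphs of at most 50 nodes for the brute-force
equivalence sweep, where exhaustive enumeration is tractable.

## Numerical and degenerate-input conventions

* Identifiers are uppercased and whitespace-stripped; symbols are otherwise
  opaque, so STRING protein IDs work wherever symbols do, reconciled
  through the alias map rather than any hard-coded ID syntax.
* The default threshold 0.400 is STRING's conventional "medium confidence"
  cutoff; it is a parameter everywhere and recorded in the run manifest.
* Duplicate edge rows keep the maximum confidence — a conservative union
  when the same interaction is reported through several channels or in
  both orientations.
* Components, candidate rankings and all written artifacts are ordered
  deterministically, so identical inputs yield byte-identical outputs.
* Empty gene lists, self-loops, malformed or out-of-scale confidence
  scores, seeds outside the universe, and assignment requests for genes
  missing from the network all fail loudly (or warn and report, where the
  row can simply be dropped) rather than being silently repaired.

## Limitations

* The bridge score is a heuristic over STRING-style combined confidences;
  it has no probabilistic calibration, and a bridged gene is a hypothesis
  generator, not a significance statement.
* Single-intermediate bridging cannot connect a gene that is two or more
  hops from the module; such genes are reported unbridgeable by design.
* Label propagation extrapolates compartments from interaction counts
  alone; proteins genuinely active in several compartments get exactly one
  group.
* Localization quality degrades as inter-block density approaches
  intra-block density — the acceptance checks quantify this on planted
  scenarios — and a thin seed set in a sparsely connected group can leave
  genes unassigned rather than guessed.
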