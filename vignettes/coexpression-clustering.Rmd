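---
title: "Clustering transcriptional responses by coexpression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering transcriptional responses by coexpression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexcluster)
```

## The analysis in one paragraph

A transcriptional response measured as replicate log2 expression differences
is summarized per gene (mean and sample standard deviation), ranked, and cut
to the strongest `n_hits` genes per direction (250 by default, non-coding
genes excluded after the cut). Each hit's top-`K` coregulated partners
(`K = 40` by default) are retrieved from a precomputed coexpression database,
and the `(K+1)²` pair matrix over every hit neighborhood is enumerated —
420,250 connection slots for 250 hits at `K = 40`. Pairs in which both genes
are hits become weighted edges; connected groups of hits are the response's
clusters. Two rank-sum statistics quantify the result: the **CoRegScore**
asks whether the genes the database predicts as coregulated with the hits
are indeed strongly regulated, and the **UpRegScore** asks how strongly any
gene set (typically a cluster) is up- or downregulated in any experiment's
ranking. Both are tested against null distributions built from 100 random
gene lists analyzed identically; cluster membership can additionally be
compared against a genome-wide transcription-factor target ranking split
into an activated (Class I) top block and a repressed (Class II) bottom
block.

## The two scores

Both scores compare a sum of 1-based ranking positions with its best- and
worst-case placements and map the result onto $[-100, 100]$:

$$\mathrm{score} = 100 - 200\,
  \frac{\mathrm{real} - \mathrm{best}}{\mathrm{worst} - \mathrm{best}}.$$

For the **UpRegScore** of a set with $n$ genes found in a ranking of $G$
genes, best $= 1 + \dots + n$ and worst $= (G-n+1) + \dots + G$: 100 means
the set occupies the very top of the ranking, $-100$ the very bottom. Genes
not measured in an experiment are *omitted* and $n$ shrinks — both the best
and worst sums are recomputed with the evaluated count, rather than
assigning omitted genes a penalty position. The 1-based convention is forced
by the extremes: any other origin fails to reach exactly $\pm 100$.

For the **CoRegScore** of $m$ predicted genes against a ranking with an
`n_hits`-gene hit block, best is the block immediately following the hits,
positions `n_hits + 1, ..., n_hits + m` — a perfect prediction means the
predicted genes are exactly the next most-regulated genes after the hits —
and worst is the bottom $m$ positions. The score is an error (undefined),
not 0, when no gene can be evaluated, and the degenerate ranking in which
best and worst coincide is rejected.

Predicted genes are the non-hits with the largest summed multiplicity
counts over all hit neighborhoods that list them; `m_predicted` defaults to
50, matching the "next 50 after the hit block" framing of the ideal case.

## Edge weights and the connection-slot count

Within one hit's neighborhood (the hit plus its `K` partners), the
contribution of a pair $(a, b)$ is the product of the two genes'
multiplicity counts in that list (the anchoring hit counts once); weights
sum over all neighborhoods containing the pair. A mutual single listing
between two hits therefore yields one edge of weight 2, and a pair marked
coexpressed several times in the database accumulates a large weight —
which is what the *connections per hit* metric reports. All `(K+1)²` slots
per database-covered hit are counted as *considered pairs* whether or not
an edge materializes; pairs between two non-hit partners are never
materialized (with predicted genes integrated, hit–predicted edges are, but
predicted–predicted pairs are not). Hits absent from the database stay in
the network as isolated, flagged nodes.

## Clusters

The reference workflow reads clusters off a force-directed layout by eye;
that is not testable, so cluster assignment here is a deterministic rule:
connected components with at least `min_size` nodes (default 3) become
numbered clusters, ordered by decreasing size with ties broken by the
lexicographically smallest member. Nodes outside every marked cluster are
labeled `"0"`, database-absent hits `"-"`. With `refine = TRUE`, components
are further split by greedy modularity (weighted fast-greedy communities),
and an unassigned node whose neighbors span two or more marked clusters
gets their `"+"`-joined label — a gene sitting between clusters. Manually
curated groupings can be supplied as an override table and take precedence
gene by gene.

## Significance

Every connectivity or score observation is compared with the same metric
evaluated on `n_null_lists = 100` random gene lists of equal size, sampled
uniformly without replacement from the analyzed gene universe (all genes in
the expression table; a coding-only universe is a caller choice). The
summary is a Z-score against the null mean and standard deviation with a
one-tailed standard-normal p-value — upper tail for upregulation and
connectivity, lower tail for downregulation. A smoothed empirical tail
probability is reported alongside, since the normal tail extrapolates
beyond what 100 lists can support. Below roughly 20 genes the null standard
deviation grows noticeably (it scales like $1/\sqrt{n}$), so small clusters
carry weaker significance at the same score — the package reproduces this
behavior and reports the null parameters so it is visible. No
multiple-testing correction is applied across clusters; p-values are raw
and documented as such.

## Target-class enrichment

A genome-wide target ranking assigns Class I to the top `n_class1`
positions and Class II to the bottom `n_class2`; membership is purely
positional. For a cluster, the observed target percentage is computed over
the cluster genes found in the ranking (missing genes change nothing), the
expected percentage is the genome-wide target fraction — with the published
class sizes 1663 and 1733 over 19,286 genes it rounds to 18% — and the
"expected by chance" comparison is an exact binomial test. The test
direction defaults to enrichment (`greater`); the reference analysis names
no test, so this choice is ours, and both combined and per-class
percentages are reported because an activated cluster may be enriched
specifically in Class I.

## The synthetic world

The generator plants disjoint modules in a synthetic genome. A module is a
gene set with (i) a regulation effect per experiment — its members' mean
log2 shift, 0 for non-members — and (ii) a coexpression fidelity $f$: each
slot of a member's top-`K` partner list points at a random co-member with
probability $f$ and at a uniformly drawn non-member otherwise, with
partners distinct within a list. Non-module genes get uniform partner
lists. Multiplicities are drawn from {1, 2, 3} with probabilities (0.6,
0.3, 0.1). Replicate values add Gaussian noise (`noise_sd`, default 1 log2
unit) to the planted effect; an optional per-replicate scale factor
emulates replicates that differ in response strength, and per-experiment
missing fractions emulate platforms that did not measure some genes. The
target-ranking emitter places each member of a chosen module inside the
Class I block with probability `strength`. Everything is a pure function of
parameters and seed.

Two presets fix the validation conditions. `"desk"` (G = 2000, three
60-gene modules with effects +3/+2.5/−3, $f = 0.9$, noise 1, three
replicates, K = 40, a companion experiment sharing only the first module
with 5% missing genes) keeps tests fast. `"paper_scale"` (G = 26,959 — a
full microarray's transcript count — with a single 60-gene module, effect
+3, noise 1, $f = 0.9$) is used for genome-scale parameter recovery: the
top-250 selection recovers the module essentially completely, and the
module-list network reaches 100% hit inclusion while an equal-sized random
list stays near the collision baseline (~20%).

What the generator does **not** emulate matters for interpreting green
tests. First, partner lists outside modules are uniform, whereas real
coexpression databases have hubs and correlated neighborhoods; at desk
scale (K = 40 lists over 2000 genes) the random-list baseline is dense —
random 60-gene lists reach ~90% inclusion by collisions alone — so the
planted-vs-random contrast is asserted on connections per hit (three orders
of magnitude) rather than on inclusion, which only separates cleanly at
genome scale. Second, a planted module is a step function: members shift,
non-members do not. Real responses are graded, with regulated genes
continuing past any hit cutoff; it is exactly those genes that make
database predictions score highly in real data. A module sitting entirely
inside the hit list leaves nothing predictable outside it, so the
CoRegScore of a synthetic top-250 analysis hovers near its null no matter
how clean the module is — the score's machinery (extremes, oracle
equivalence, null behavior) is fully testable, but its headline magnitude
on real data is not reproducible from this generator by construction.

## Numerical and interface choices

* Replicate standard deviation uses the sample ($n-1$) estimator, the
  spreadsheet default; a single present value gives sd 0 by convention, and
  genes with no present value are dropped with a warning.
* Ranking ties break lexicographically by gene id, everywhere, so all
  outputs are deterministic; position sums use exact block formulas.
* The display bins follow the four-shade legend with strict thresholds
  (±0.25, ±1); boundary values fall to the weaker bin, so the five bins
  partition the line.
* Non-coding genes are removed after taking the top-`n` (no refill), which
  can leave a hit list short; `refill = TRUE` restores the requested size
  from further down the ranking.
* The hit-selection, network, and score stages validate their
  preconditions and fail with named errors (duplicate gene ids, duplicate
  partner ranks, empty predictions, degenerate rankings) rather than
  returning sentinel values.
* Problem sizes in the shipped validation: score oracles are exhaustive up
  to G = 8; null-behavior checks use 100 lists over a 1000-gene universe;
  the pipeline determinism and integration checks run a 2000-gene world
  with 80-gene hit lists and 25-list nulls; parameter recovery runs the
  26,959-gene preset once with 100-list nulls.

## Limitations

Cluster assignment by connected components can merge visually distinct
subclusters when modules share even sparse chance edges; the modularity
refinement and the override table exist for that case. The normal-tail
p-value assumes the null scores are approximately Gaussian, which holds
well for the rank sums of lists of ≥ 20 genes but is an extrapolation in
the far tail. And as discussed above, synthetic validation exercises the
machinery and its contrasts, not the field-data magnitudes of the scores.
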