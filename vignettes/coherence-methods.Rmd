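---
title: "Measuring size-normalized coherence of gene-set interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring size-normalized coherence of gene-set interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A phenotype-associated gene set is *coherent* when its genes form a
community within the global protein–protein interaction (PPI) network:
many interactions among themselves, relatively few with the rest of the
interactome. `netcoherence` turns this graph-theoretic intuition into a
single comparable number per gene set.

For a set $S$ and a global network $G$, each member gene $g$ present in $G$
has an internal degree $k_{int}(g)$ (neighbors inside $S$) and an external
degree $k_{ext}(g)$ (neighbors outside $S$); by construction
$k_{int} + k_{ext}$ is the gene's global degree. Members without any
interaction annotation are excluded; members with $k_{int} = 0$ but
$k_{ext} > 0$ are kept, since they still inform the external degree
distribution. The raw statistic is the least-squares slope through the
origin of $\sqrt{k_{ext}}$ on $\sqrt{k_{int}}$:

$$\hat\beta \;=\; \frac{\sum_g \sqrt{k_{int}(g)}\,\sqrt{k_{ext}(g)}}
                      {\sum_g k_{int}(g)}.$$

A maximally coherent set (complete internal wiring, no external edges) lies
on a horizontal line, $\hat\beta = 0$; random sets, whose few internal
edges are dwarfed by external ones, produce steep slopes. Forcing the fit
through the origin encodes the natural anchor: a gene with no internal
interactions provides no evidence about the internal-vs-external trade-off.

**Assumptions.** Edges are undirected, unweighted and reliable after the
confidence filter; the input set is the complete current knowledge of the
phenotype's genes; the global network is large relative to the set, so
external degrees are effectively unconstrained by set membership.

## Why raw slopes are not comparable, and the normalization

Degree distributions depend on network size: a 10-node and a 20-node
complete network are equally coherent yet have degrees 9 and 19. Raw slopes
correlate negatively with set size for both pathway-like and random sets
(the package's size diagnostic reproduces this on synthetic panels). The
remedy is min–max normalization against *size-matched* references:

* $\beta_{min}$ — the median slope of 30 networks from user-designated
  high-coherence collections (10 per collection for 3 collections, the
  nearest-in-size sets from each), and
* $\beta_{max}$ — the median slope of $n_{random}$ uniform random gene sets
  of the same effective size;

$$\beta_{norm} = \frac{\beta - \beta_{max}}{\beta_{min} - \beta_{max}}.$$

Coherence is 0 at the random median and 1 at the reference median.
Values are *not* clamped: a particularly dense set can exceed 1, and random
fluctuation puts individual random sets slightly below 0; both are
informative. Normalization is undefined when $\beta_{min} = \beta_{max}$
(a degenerate panel), which is raised as an error rather than silently
returning 0/0.

"Matched in size" means matched on *effective* size — the number of set
genes present in the network — because degree tables exist only over present
genes. Matching is nearest-absolute-difference with lexicographic
tie-breaks; reference sets are never subsampled to force an exact match,
since subsampling would destroy the very pathway structure that makes them
references.

## Eligibility filters

Two filters precede any fit, both reported per phenotype rather than
silently dropping it:

* **too_few_nonzero** — fewer than `min_nonzero` (default 10) genes with
  $k_{int} \ge 1$. Small internal-degree samples make the slope unstable; a
  larger threshold can be configured.
* **degenerate_internal_degrees** — all retained genes share one internal
  degree value, so there is no internal degree distribution to regress.
  The test covers genes with $k_{int} = 0$ as well: a table of all-zero
  internal degrees is the extreme degenerate case.

## Confidence intervals

The CI is the standard normal-theory interval for a through-origin
regression: $\hat\beta \pm t_{1-\alpha/2,\,n-1}\,
\sqrt{RSS/(n-1)/\sum x^2}$ with $n$ the number of table rows. Rows with
$k_{int} = 0$ contribute nothing to $\hat\beta$ algebraically but do enter
$n$ and the residual sum, widening the interval — they represent genuine
uncertainty about the set's internal connectivity. CI bounds are normalized
exactly like the slope; because the map is decreasing the bounds swap and
are re-sorted. Normalization distorts the usual CI interpretation, so the
permutation test, not the normalized CI, is the instrument for comparing
coherences. The test suite cross-checks both the slope and its CI against a
generic linear-model fit and against brute-force one-dimensional
minimization of the residual sum.

## Permutation test

The null is "a random gene set of the same size and the same number of
non-zero interacting genes". A single uniform draw of size $g$ from a
sparse interactome rarely reaches the phenotype's non-zero count $n_i$, so
random networks are *assembled*: repeated draws of size $g$, harvesting
from each draw the genes interacting within that draw, accumulated until
$\ge n_i$ genes are collected. Each assembled set is scored with the same
degree-table-plus-slope machinery as the phenotype (degrees computed
against the full interactome, internal meaning within the combined set),
which keeps observed and null statistics exchangeable. With add-one
smoothing, $p = (\text{count} + 1)/(n_{perm} + 1) \in (0, 1]$, attaining
$1/(n_{perm}+1)$ at best.

**Tail direction.** Counting random slopes *greater* than the observed one
makes small $p$ mean "less coherent than random", which contradicts the use
of the test to flag significantly coherent phenotypes. The package
therefore defaults to `tail = "coherent"` (count of random slopes
$\le \beta_{obs}$, small $p$ = more coherent than random), and keeps the
literal greater-than convention available as `tail = "larger"` for audit.

`n_perm` defaults to 10,000; tests and examples use 99–999, which is enough
to resolve the planted-versus-random contrast at desk scale.

## Modularity comparison

Greedy agglomerative modularity maximization (Clauset–Newman–Moore, via
igraph) is run on the subgraph induced by the set's *internal* edges only,
and the partition's $Q$ is reported next to coherence. The two metrics are
deliberately different: a set splitting into several disconnected dense
clumps is highly modular but only moderately coherent as a whole. Exhaustive
partition search on small graphs confirms the greedy optimum on the
benchmark cases (two disjoint triangles, $Q = 0.5$; complete graphs,
$Q = 0$) and bounds it elsewhere.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `score_threshold` | 500 | STRING confidence filter, strict `>`, on the 0–1000 scale (midpoint of the score's bimodal distribution) |
| `taxon_id` | "9606" | BioGrid organism filter on both interactors |
| `min_nonzero` | 10 | minimum non-zero interacting genes |
| `per_collection` | 10 | size-matched reference sets per collection |
| `n_random` | 1000 | random sets per panel |
| `n_perm` | 10000 | permutations |
| `ci_level` | 0.95 | slope CI level |
| `tail` | "coherent" | permutation tail (see above) |

All stochastic stages derive their streams from one config seed via
`stage_seed()`, so a full pipeline rerun is byte-identical, and panels are
seeded per target size, making results independent of phenotype order.

## The synthetic world

`generate_world()` builds the complete study environment in memory and
(`write_world()`) on disk in the exact dialects the readers consume, so
every pipeline stage is testable without downloads. It emulates:

* a **background interactome** — Erdős–Rényi by default (2000 genes, edge
  probability 0.005, matching a realistic mean degree of ~10), or
  preferential attachment when a heavy-tailed degree distribution matters;
* **reference collections** — 3 collections × 10 planted modules (sizes
  20–80, internal wiring probability 0.6, external attachment at background
  rate), standing in for curated pathway collections;
* **phenotypes** at controlled coherence: `high` ($p_{in} = 0.8$),
  `medium` ($p_{in} = 0.3$), and `random` (plain uniform draws).

Planted member sets are disjoint so ground-truth levels stay
uncontaminated. By default members are drawn from existing background
genes and keep their background edges — realistic, but it means the
realized external rate is the background rate plus $p_{out}$.
`plant_module(..., fresh_symbols = TRUE)` instead mints brand-new genes
carrying exactly the wired edges; this mode makes controlled constructions
exact (a $p_{in}=1, p_{out}=0$ module is a perfect clique with slope 0, and
a module wired at background density is statistically indistinguishable
from a random draw) and is what the corresponding tests use.

What the generator does **not** emulate: the empirical degree distribution,
clustering and core–periphery structure of real interactomes; annotation
ascertainment bias (well-studied genes have more recorded interactions);
overlap between pathways and phenotypes (planted sets are disjoint by
design). Passing tests therefore demonstrate the estimator's statistical
behavior under known ground truth, not the biological accuracy of any
particular PPI database.

One consequence of planting modules into the world is that "random" draws
from it are mildly structured: a draw can hit two genes of the same planted
module and inherit a dense edge. This mirrors reality — random gene sets
from a real interactome also contain pathway fragments — and is handled
correctly because the random reference panel is drawn from the same world
as the queries.

## Numerical and design choices

* **Square root on both axes.** The transform stabilizes count variance and
  is applied to internal and external degrees symmetrically, preserving the
  slope-1 identity for sets whose internal and external degrees coincide.
* **Strict score inequality** (`> 500`, not `≥`) for STRING filtering; the
  boundary case is covered by a test.
* **Trait-cell delimiters** for mapped-genes columns default to `";"`,
  `","`, `" - "`, `" x "` and are configurable; gene-class exclusions
  (non-coding, antisense, readthrough) are a user-supplied list plus
  optional regular expressions rather than a hard-coded annotation
  database.
* **`n_random`** defaults to 1000; 100–200 already gives a stable median
  at desk scale and is what the tests and the acceptance script use.
* **Reference shortage** (a collection smaller than `per_collection`)
  degrades gracefully — all sets are used with a warning; a panel with
  fewer than 3 usable reference slopes is an error.
* **Assembly caps.** Random-network assembly stops with an explicit error
  after 10,000 draws (pathologically sparse networks), rather than looping
  forever.
* **Panel caching** is keyed by target size inside a pipeline run; the
  per-size seeding makes the cache semantically transparent.

## Problem sizes used by the tests and the acceptance script

The shared test world is the default 2000-gene world; panels in tests use
100 random sets; the permutation-based recovery checks use 500
permutations; the size-independence check spans 50 sizes between 20 and 200
with 20 replicates each; the planted-ordering property averages over 20
independently seeded 800-gene worlds. The acceptance script builds a
2000-gene world with 30 reference modules of sizes 20–60 and a panel of 200
random sets at target size 40. These sizes were chosen as the smallest
configurations at which the medians and correlations involved are stable.

## Known limitations

* Coherence inherits the biases of the chosen PPI database; sets with
  little interaction annotation are ineligible rather than estimated.
* Very large gene sets can contain outlier genes with extreme internal
  degrees, inflating coherence above 1.
* Only one modularity algorithm (greedy agglomeration) is offered, and
  modularity is not size-normalized — comparing modularity across sizes has
  the same problem coherence normalization solves, and is out of scope.
* Weighted or directed interactions are not modeled; confidence scores are
  used only for thresholding.
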