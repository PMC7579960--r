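# netcoherence

Genes associated with a phenotype (for example, the mapped genes of a GWAS
trait) are expected, when the underlying molecular mechanism is coherent, to
form a community inside the global protein–protein interaction (PPI)
network: densely connected among themselves, comparatively sparsely
connected to everything else. `netcoherence` quantifies this for a gene set
of any size and makes the estimates comparable across phenotypes.

It is aimed at systems-biology analyses that start from a global interactome
(STRING-style links or BioGrid TAB files), curated pathway collections
(GMT), and phenotype gene lists (a trait table with a mapped-genes column).

## The statistic

For a phenotype gene set *S* inside a global PPI network, every gene *g ∈ S*
that carries interaction annotation has an **internal degree**
*k*<sub>int</sub>(*g*) (partners inside *S*) and an **external degree**
*k*<sub>ext</sub>(*g*) (partners outside *S*). The raw coherence is the
least-squares slope **through the origin** of the square-root-transformed
degrees,

&nbsp;&nbsp;&nbsp;&nbsp;β = Σ √*k*<sub>int</sub> √*k*<sub>ext</sub> / Σ *k*<sub>int</sub>,

so a fully internally connected set with no external edges has β = 0 (a
horizontal line) and progressively more random sets have progressively
larger slopes. Raw slopes shrink with network size, so they are not
comparable across phenotypes. They are therefore min–max normalized against
two *size-matched* references: the median slope β<sub>min</sub> of 30
networks from high-coherence pathway collections (10 per collection) and the
median slope β<sub>max</sub> of *n* random gene sets of the same effective
size:

&nbsp;&nbsp;&nbsp;&nbsp;β<sub>norm</sub> = (β − β<sub>max</sub>) / (β<sub>min</sub> − β<sub>max</sub>).

Normalized coherence is 0 at the random median, 1 at the pathway median, and
is deliberately not clamped (values slightly above 1 occur and are
meaningful). Significance against random networks is assessed with a
permutation test over assembled random networks matched in size and in the
number of non-zero interacting genes, with add-one smoothing
*p* = (count + 1)/(*n*<sub>perm</sub> + 1). Greedy
(Clauset–Newman–Moore) modularity of the internal subgraph is reported
alongside, because coherence and modularity capture distinct network
properties.

Phenotypes with fewer than 10 non-zero interacting genes, or whose internal
degrees are all identical (no internal degree distribution to regress), are
reported as ineligible rather than fitted.

## Worked example

Everything is testable without downloads: the package generates synthetic
interactomes with planted dense modules at known coherence levels and writes
them in the exact on-disk dialects the readers consume.

```r
library(netcoherence)

dir <- "demo"
cfg <- list(
  seed = 42, output_dir = dir,
  simulate = list(n_genes = 1500, background_p = 0.005,
                  n_collections = 3, modules_per_collection = 8,
                  module_size_range = c(20, 50),
                  phenotype_levels = c("high", "medium", "random"),
                  phenotype_sizes = c(40, 40, 40)),
  ppi = list(path = file.path(dir, "links.txt")),
  references = file.path(dir, paste0("collection_", c("A", "B", "C"), ".gmt")),
  phenotypes = list(path = file.path(dir, "phenotypes.tsv"),
                    category_column = "CATEGORY"),
  per_collection = 8, n_random = 200, n_perm = 999)

run_simulate(cfg)    # writes links.txt, *.gmt, phenotypes.tsv, manifest.json
run_coherence(cfg)   # writes results.tsv + summary.tsv
run_permtest(cfg)    # adds the perm_p column
```

The run prints one line per phenotype and produces `demo/results.tsv`:

```
set_id          category n_genes n_nonzero slope    ...  coherence   perm_p  modularity reason
pheno_high_01   high     40      40        0.774906 ...  1.04399     0.001   0.0415947  ok
pheno_medium_02 medium   40      40        1.27209  ...  0.910138    0.001   0.170981   ok
pheno_random_03 random   40      18        4.75442  ... -0.0273575   0.777   0.785714   ok
```

The planted dense module (internal wiring probability 0.8) scores coherence
1.04 — slightly *above* the median reference pathway — at the minimum
attainable p-value 1/(999 + 1); the medium module (0.3) scores 0.91; the
plain random draw sits at ≈ 0 with p = 0.78, i.e. indistinguishable from the
random reference. Note the random set's high modularity (0.79): its few
internal edges split into small disconnected clumps, which is exactly why
modularity is not a substitute for coherence.

The same functions run on real data: point `ppi$path` at a STRING
`protein.links` file (scores are filtered at `combined_score > 500` by
default) or a BioGrid TAB file (`ppi$dialect = "biogrid"`), `references` at
GMT files of pathway collections, and `phenotypes$path` at a trait table
with a `MAPPED_GENE` column. A thin command-line wrapper is installed at
`inst/cli/netcoherence.R` with subcommands `simulate`, `coherence`,
`permtest`, `report`.

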