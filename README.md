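# driverMCL

Identification of **cancer driver modules** — sets of functionally
related genes whose somatic mutations jointly drive tumor progression —
from binary mutation matrices, by combining three module properties:

* **mutual exclusivity** of mutations (members of a driver module tend
  to mutate in *different* patients),
* **functional similarity** of genes, derived from a weighted gene
  functional interaction network (HumanNet-style log-likelihood
  scores), and
* **connectivity** in a protein–protein interaction (PPI) network.

The package is aimed at cancer genomics analysts working with
cBioPortal-style mutation exports plus public interaction networks
(Multinet, HumanNet), and at methodologists who want a reproducible
simulation benchmark for exclusivity-based module detection.

## Method

For a gene set *se* on the binary mutation matrix, with coverage
*C(se)* (fraction of samples with ≥ 1 mutated member) and coverage
overlap *O(se)* (fraction with ≥ 2), mutual exclusivity is

```
ME(se) = C(se) − O(se)
```

Mutation calls can first be sharpened with Cancer Cell Fraction (CCF)
values: per gene, the lowest-CCF mutation is dropped, and mutations
whose CCFs lie within ε (default 0.1) of a higher-CCF survivor are
removed in a descending sweep.

Functional scores are min–max normalized, `LS_N = (LS − LS_min) /
(LS_max − LS_min)`, pairwise gene similarity is `S(g_i, g_j)` (1 on the
diagonal, `LS_N` on functional edges, 0 otherwise), and the similarity
of two PPI nodes is the Best-Match Average over their PPI neighborhoods
G_i, G_j:

```
S^P_ij = [ Σ_{g∈G_i} S(g, G_j) + Σ_{g∈G_j} S(g, G_i) ] / (|G_i| + |G_j|)
```

Each PPI edge between mutated genes is weighted by the product

```
ws(pg_i, pg_j) = ME(pg_i, pg_j) × S^P_ij
```

and the weighted graph is clustered by **Markov clustering (MCL)**:
column-normalize the transition matrix (self-loops = max incident
weight), then alternate expansion `P·P` with inflation (entrywise power
*rp* = 2 + renormalization) until convergence; rows retaining flow are
attractors and define the clusters. Candidate clusters are refined by a
**permutation test** on group exclusivity (gene-wise column permutation
null, add-one p-value); non-significant clusters are recursively
decomposed into subgroups down to size 3 and the most significant
subgroup is kept. Recovered modules are reported with their ME,
p-value, and mean internal edge weight *ws*.

A built-in simulator plants perfectly exclusive modules into a
patients × genes matrix, adds symmetric flip noise and Bernoulli
passenger mutations, and generates companion PPI/functional networks
(planted cliques over a random background), so the full pipeline runs
and can be benchmarked (gene-level precision/recall/F1) with no
external downloads.

## Worked example

```r
library(driverMCL)

ds <- generate_dataset(sim_config(n_samples = 80, n_genes = 30,
                                  module_sizes = 4L, noise = 0.03,
                                  passenger_rate = 0.05, seed = 91))
mods <- find_driver_modules(ds$M, ds$ppi, ds$nf,
                            perm_cfg = permutation_config(n_permutations = 300,
                                                          seed = 92))
mods
#> 1 driver module(s)
#>   rank                   genes size     me     p_value  mean_ws
#> 1    1 g0006;g0013;g0016;g0019    4 0.8125 0.003322259 0.454807

ds$truth[[1]]
#> [1] "g0006" "g0013" "g0016" "g0019"

f1_score(select_top_modules(mods, 1), ds$truth)$f1
#> [1] 1
```

The one retained module is exactly the planted gene set: 81% of the 80
simulated patients carry exactly one mutated member (`me = 0.8125`),
the permutation test saw no null draw as exclusive in 300 permutations
(`p = 1/301 ≈ 0.0033`), and the module's PPI edges carry a mean weight
of 0.45. Scored against the planted truth the recovery is perfect
(`F1 = 1`).

Real datasets enter through `read_mutation_matrix()` (samples × genes
TSV or per-mutation pair list), `read_ccf_matrix()`,
`read_ppi_network()` and `read_functional_network()`; results are
written with `write_modules()`. A thin command-line front end with
`run`, `simulate` and `benchmark` subcommands is installed at
`inst/scripts/driver-mcl.R`.

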