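---
title: "Detecting cancer driver modules with exclusivity-weighted Markov clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cancer driver modules with exclusivity-weighted Markov clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(driverMCL)
```

## The problem

Cancer genomes accumulate many somatic mutations, but only a minority
drive tumor progression. Driver genes tend to act in concert through
pathways, and within such a *driver module* the mutations of different
members are typically **mutually exclusive** across patients: once one
member is mutated, mutations in the others confer little extra selective
advantage. Exclusivity alone, however, is a weak signal at realistic
sample sizes — random sparse mutations also rarely co-occur. driverMCL
therefore combines three module properties:

1. mutual exclusivity of somatic mutations,
2. functional similarity of the genes, derived from a weighted gene
   functional interaction network (HumanNet-style log-likelihood
   scores), and
3. connectivity in a protein–protein interaction (PPI) network.

## The model

### Exclusivity

For a gene set $se$ on a binary mutation matrix $A$ (samples $\times$
genes), coverage $C(se)$ is the fraction of samples with at least one
mutated member and coverage overlap $O(se)$ the fraction with two or
more. Mutual exclusivity is

$$ME(se) = C(se) - O(se),$$

the fraction of samples carrying *exactly one* mutated member. It lives
in $[0, 1]$ and is 1 only for a perfectly exclusive set covering every
sample.

### CCF filtering

When Cancer Cell Fraction values are available, the mutation matrix is
sharpened before scoring. The CCF of a mutation is the proportion of
cancer cells in the sample that carry it; clonal (early) mutations have
high CCF, and low-CCF calls are weaker evidence. Per gene, the filter
(a) deletes the single mutation with the lowest CCF (only when the gene
has at least two mutations — `min_mut_for_trim = 2` — since deleting a
singleton gene's only mutation would erase the gene), and (b) scans the
remaining mutations in descending CCF order, deleting any mutation whose
CCF lies within $\varepsilon$ of the current survivor, and advancing the
survivor otherwise. The sweep makes the near-tie rule deterministic and
order-independent (ties broken by sample id), and it is idempotent: a
second pass changes nothing. The default $\varepsilon = 0.1$ balances
retained signal against module count; it is exposed as a parameter (and
as `--epsilon` on the command line). Simulated data carry no CCF layer,
so the filter is bypassed in all simulation experiments.

### Functional similarity

Raw log-likelihood scores $LS$ of the functional network are min–max
normalized over the whole network,
$LS_N = (LS - LS_{\min}) / (LS_{\max} - LS_{\min})$ (if every score is
equal the range is degenerate and all scores are set to 1 with a
warning). Pairwise gene similarity is
$S(g_i, g_j) = 1$ if $g_i = g_j$, $LS_N(g_i, g_j)$ for a functional
edge, and 0 otherwise. Similarity of a gene to a set is its best match,
$S(g_n, G) = \max_{g \in G} S(g_n, g)$, and similarity of two PPI nodes
is the Best-Match Average over their PPI neighborhoods $G_i$, $G_j$:

$$S^P_{ij} = \frac{\sum_{g \in G_i} S(g, G_j) + \sum_{g \in G_j} S(g, G_i)}{|G_i| + |G_j|}.$$

Two design points were genuinely open. First, $G_i$ excludes the node
itself: including it would reward hubs with inflated self-matches.
Second, the neighborhoods are taken from the PPI network (not the
functional network), since $S^P$ is introduced as a similarity *of PPI
nodes*; the functional network only supplies the pairwise scores. A node
with no PPI neighbors gets $S^P = 0$ (with a warning) rather than an
error — such isolated genes cannot join a module anyway.

### Edge weighting and Markov clustering

Every PPI edge between mutated genes is weighted by

$$ws(pg_i, pg_j) = ME(pg_i, pg_j) \times S^P_{ij} \in [0, 1],$$

so an edge is strong only when its endpoints are both exclusive and
functionally similar. Zero-weight edges are dropped; exclusivity is
computed only for PPI edges, never for all gene pairs. Genes with no
mutations are excluded before weighting: a never-mutated gene would
otherwise look perfectly "exclusive" against any partner while carrying
no evidence at all.

Candidate modules are extracted by Markov clustering (MCL) of the
weighted graph. The transition matrix starts with the edge weights off
the diagonal and a self-loop on each node equal to its maximum incident
weight (1 for isolated nodes); the self-loop rule is the standard MCL
convention and guarantees positive column sums. Columns are normalized
to sum to 1, and the algorithm alternates **expansion** (matrix
squaring, spreading flow along two-step walks) with **inflation**
(entrywise power $rp$ followed by column renormalization, sharpening
strong flows). Defaults: inflation $rp = 2$ (the canonical MCL setting;
larger values give finer clusters), at most 100 iterations, convergence
when the maximum absolute entrywise change falls below $10^{-6}$ —
the idealized "one nonzero per column" limit is never reached exactly in
floating point, and symmetric flow (e.g. a uniform triangle) settles
into a stable multi-attractor fixed point instead. Entries below
$10^{-8}$ are pruned before each renormalization for numerical hygiene.
Clusters are read off the limit matrix: rows retaining diagonal mass are
attractors, attractors drawing from a common column merge into one
attractor system, and every column joins the system holding its largest
entry (ties toward the smallest gene id). The result is always a
partition of the nodes and never spans disconnected components.

### Refinement by permutation test

MCL clusters are candidates, not modules. For each cluster of at least
3 genes (`min_module_size = 3`), the observed $ME$ is compared with its
permutation null. The default null model permutes each gene's column
independently across samples, preserving every gene's mutation
frequency — the standard null for exclusivity statistics; a stricter
"switching" model (checkerboard swaps preserving sample *and* gene
margins, sampled by a Markov chain of attempted swaps) is available but
approximate. The p-value uses the add-one estimator
$p = (1 + \#\{ME_{null} \ge ME_{obs}\}) / (1 + n_{perm})$, whose
smallest attainable value is $1/(n_{perm}+1)$; the raw exceedance count
is reported alongside, so a "zero exceedances" result remains visible.
With the default $n_{perm} = 1000$ and $\alpha = 0.05$.

A significant cluster is kept whole. A non-significant cluster of size
$r$ is decomposed into all size-$(r{-}1)$ subgroups; significant
subgroups are recorded and non-significant ones recursed into, down to
size 3, and the subgroup with the smallest p-value wins (ties: larger
$ME$, then larger size, then lexicographic gene order). The selection is
per cluster, so several modules can be reported per dataset. Tested
subgroups are memoized; clusters larger than 12 genes switch to a
greedy descent (repeatedly drop the gene whose removal maximizes $ME$),
flagged in the output, because exhaustive descent is exponential in the
cluster size. Two computational notes: the test supports adaptive early
stopping — drawing stops once the exceedance count alone guarantees that
the full run could not reach $p < \alpha$ — which leaves every
significance call and every small p-value identical to a full run while
making clearly-null subgroups cheap; and no multiple-testing correction
is applied across clusters — raw p-values are reported, as is
conventional for this family of methods, and documented as such.

## The simulator

`generate_dataset()` emulates the four input artifacts so the entire
pipeline runs with no downloads. Defaults describe the benchmark
conditions: 500 patients, 200 genes, one planted module of 4 genes at
coverage 0.9, flip noise 0.05, passenger rate 0.05.

* **Planted exclusivity.** Each planted module receives a disjoint block
  of $\lfloor \text{coverage} \times n / k \rfloor$ covered samples and
  each covered sample is assigned exactly one module gene round-robin,
  so planted columns are pairwise exclusive (also across modules) before
  noise.
* **Passengers.** Non-planted genes mutate i.i.d. Bernoulli at the
  passenger rate.
* **Noise.** Every cell is then flipped independently with the noise
  probability, so the realized flip fraction over all cells concentrates
  around the nominal noise level. Passenger columns are laid down before
  the flip step; their effective mutation rate is therefore
  approximately `passenger_rate + noise`.
* **Companion networks.** Planted-module genes form PPI cliques whose
  functional scores are drawn Uniform(4, 6); background genes receive
  Erdős–Rényi edges among themselves ($p = 0.05$) with scores
  Uniform(0, 2). After min–max normalization, planted edges score
  roughly 0.67–1 and background edges at most ~0.33. The networks are a
  simulation necessity — real functional and PPI networks are measured
  data with hubs, degree heterogeneity and annotation bias that the
  generator does not reproduce. Passing benchmarks on these data shows
  that the pipeline recovers exclusive, well-connected planted modules
  under mutation noise; it does not certify performance on real
  networks, where module genes also interact with hundreds of
  non-module partners.
* Module coverage (0.9) and the background edge probability are not
  dictated by the benchmark protocol; 0.9 mirrors the observed coverage
  of well-known driver modules (70–90% of samples), and $p = 0.05$
  gives background genes a realistic mean degree of ~10.

All randomness flows from a single integer seed, and generation restores
the caller's RNG state, so datasets are bit-reproducible.

## Scoring

Recovery is scored at the gene level: predicted module genes are pooled,
planted genes are pooled, and precision, recall and
$F_1 = 2 \cdot Pr \cdot Re / (Pr + Re)$ are computed on the pooled sets
($F_1 = 0$ when $Pr + Re = 0$). Gene-level pooling avoids the ambiguity
of matching predicted to planted modules one-to-one; per-module matching
would be a stricter alternative. When $k$ modules are planted, the top
$k$ results are selected by ascending p-value with ties broken by
descending mean internal edge weight — equivalently, the selected top
module is the one with the lowest p-value and, among those, the highest
$ws$.

`run_benchmark()` sweeps noise and passenger-rate grids with a fixed
number of replicates per cell (default 20) and derives one seed per
replicate from the master seed.

## A small worked example

```{r example}
ds <- generate_dataset(sim_config(n_samples = 80, n_genes = 30,
                                  module_sizes = 4L, noise = 0.03,
                                  passenger_rate = 0.05, seed = 91))
mods <- find_driver_modules(ds$M, ds$ppi, ds$nf,
                            perm_cfg = permutation_config(
                              n_permutations = 300, seed = 92))
mods
ds$truth[[1]]
f1_score(select_top_modules(mods, 1), ds$truth)$f1
```

## Degenerate inputs and numerical choices

* A functional network whose scores are all equal normalizes to
  $LS_N = 1$ everywhere (warning).
* Column stochasticity is tracked at every MCL iteration; the largest
  deviation observed is returned (`max_colsum_dev`) and stays below
  $10^{-9}$.
* A non-converged MCL run (iteration cap) returns the current clustering
  with a warning rather than failing.
* Exceedance comparisons in the permutation test use a $10^{-9}$
  absolute guard so that null statistics equal to the observed value are
  counted as exceedances despite floating-point rounding.
* Header-only mutation files parse to a 0-sample matrix that downstream
  operations reject explicitly.

## Limitations

* The exhaustive subgroup descent is exponential; the size-12 cap with
  greedy fallback trades completeness for tractability on large
  clusters.
* The switching null model is a Markov chain without a formal mixing
  guarantee; the gene-wise model is the default and the one used in all
  benchmarks.
* Simulated companion networks are idealized (cliques + Erdős–Rényi);
  see the simulator section for what benchmark results do and do not
  imply.
* Real-data workflows (cBioPortal mutation exports, Multinet, HumanNet)
  are supported through the readers, but no real dataset ships with the
  package.
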