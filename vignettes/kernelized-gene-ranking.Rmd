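---
title: "Kernelized score functions for gene ranking on functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernelized score functions for gene ranking on functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernrank)
```

## The problem

Gene modules — coherent sets of genes such as the cancer modules curated from
tumour expression compendia — are incomplete: a gene absent from a module may
simply never have been assayed in the right condition. Functional interaction
networks (protein–protein and domain–domain interactions, co-expression,
comparative-genomics links) provide an orthogonal signal: genes that interact
tend to share function. `kernrank` ranks every gene in a network by how likely
it is to belong to a given module, given only the module's current members as
positive labels. No negative labels exist in this setting; everything outside
the module is merely *unlabeled*. This is semi-supervised, guilt-by-association
gene prioritization.

## The model

### Random walk kernels

Let $W$ be the symmetric non-negative adjacency of the network and
$D = \mathrm{diag}(d_i)$, $d_i = \sum_j w_{ij}$, its degree matrix. The
one-step random walk kernel is

$$K = (a - 1)\,I + D^{-1/2} W D^{-1/2}, \qquad a > 1 .$$

The spectrum of $D^{-1/2} W D^{-1/2}$ lies in $[-1, 1]$, so $a > 1$ makes $K$
positive semidefinite: a valid kernel, i.e. an inner product
$K(v, x) = \langle \phi(v), \phi(x) \rangle$ in an implicit feature space.
The $q$-step kernel is the matrix power $K^q$ (computed by repeated
multiplication); it connects genes joined by paths of up to $q$ edges, so
$q = 2$ credits genes that share a neighbour even without a direct edge.

Defaults are $a = 2$ and $q = 2$: one diagonal-shift unit keeps the kernel
well-conditioned without drowning the topology, and two steps capture direct
plus common-neighbour similarity, which is where module signal concentrates;
longer walks mix in increasingly remote, noisier relationships.

### Score functions

Given a module's positive set $V_C$, each candidate $v$ is scored by a negated
feature-space distance to $V_C$, evaluated through kernel entries only:

* **Average score** $S_{AV}(v) = -K(v,v) + \frac{2}{|V_C|}\sum_{x \in V_C} K(v,x)$
* **Nearest-neighbour score** $S_{NN}(v) = 2\max_{x \in V_C} K(v,x)$
* **k-nearest-neighbour score** $S_{kNN}(v) = 2\sum_{x \in I_k(v)} K(v,x)$,
  where $I_k(v)$ holds the $k$ positives with the largest $K(v, x)$

Higher score, higher likelihood of membership. The default $k = 27$ sits
between the extremes: $k = 1$ is $S_{NN}$ (sensitive to single spurious
edges), $k \ge |V_C|$ averages over the whole module (diluting signal for
candidates attached to one sub-cluster); $k$ is clamped to $|V_C|$ when the
module is smaller.

$S_{NN}$ and $S_{kNN}$ as written drop the diagonal terms $K(v,v)$ and
$K(x,x)$ of the underlying distances, which is exact when the kernel diagonal
is constant. That premise holds at $q = 1$ (the diagonal is $a - 1$
everywhere) but **fails for $q \ge 2$**, where the diagonal varies with local
topology. The simplified forms are nonetheless the default scoring methods,
because they are the forms the experiments in this field report;
`score_full_similarity()` exposes the un-simplified distances (all diagonal
terms kept) so the approximation can be audited. $S_{AV}$ keeps its own
$-K(v,v)$ term always and differs from the full average similarity only by a
candidate-independent constant, so its ranking is exact at every $q$. The
test suite verifies all of this against an explicit eigendecomposition
embedding $\phi(v) = \Lambda^{1/2} U^\top e_v$.

Scores can be negative (the codomain is the reals); only the induced ranking
matters. All ties — in scores, and in the selection of $I_k(v)$ at the $k$-th
position — break lexicographically on gene identifier, so every ranking is
deterministic and seed-free.

Complexity: once $K$ is built (label-free, so once per network, reused across
modules and cross-validation folds), scoring all candidates for one module
reads $|V| \cdot |V_C|$ kernel entries. The `ops` attribute on every score
vector counts exactly the entries read, which the tests use to check the
linear scaling.

## Comparison methods

**Gaussian random field propagation** (`zhou_solve`) minimizes
$\alpha \sum_i (s_i - s^0_i)^2 + (1 - \alpha) \sum_{ij} w_{ij} (s_i - s_j)^2$;
the unique minimizer solves $(\alpha I + (1-\alpha) L)\,S = \alpha S^0$ with
$L$ the combinatorial Laplacian of the normalized adjacency. The quadratic
form is applied to the *normalized* matrix because that is what the
integration pipeline feeds every method. Direct solve by default; conjugate
gradient (tolerance $10^{-8}$) above 5000 genes. Default $\alpha = 0.5$
weighs both terms equally; it is exposed as a parameter.

**GeneMANIA variant** (`genemania_solve`): same solver, cost-sensitive labels
$s^0_i = +(n - n_+)/n$ for positives and $-n_+/n$ otherwise (zero-mean,
class-prior-balanced — the convention of the GeneMANIA literature; the
original constants are not uniquely pinned down, so ours is documented rather
than asserted). A consequence worth knowing: on a single network the
cost-sensitive labels are the binary labels minus the constant $n_+/n$, and
the system matrix maps constants to $\alpha^{-1}$-scaled constants, so the
GeneMANIA solution is the Zhou solution shifted by a constant — identical
rankings. The technique matters when combined with the `sw_integrate`
weighted integration, and the reduction is itself a test oracle.

**Label propagation** (`labelprop_solve`) minimizes the smoothness term alone
with the labeled scores clamped: the harmonic solution
$s_u = \sum_j w_{uj} s_j / \sum_j w_{uj}$, solved directly on the unlabeled
block (iterative propagate-and-clamp fallback available). With only positive
labels clamped — all this ranking task provides — the exact harmonic solution
is constant on every connected component touching a clamped gene, so
converged label propagation ranks at chance level here. We implement and
report it faithfully rather than altering it; partially-converged iterative
variants would behave differently, but that is a different estimator. Genes
with no path to any clamped gene are unconstrained and are pinned to 0 with a
warning.

## Network handling and integration

Networks load from TSV edge lists or named adjacency matrices. Conflicting
duplicate edge weights resolve by maximum (conservative retention of the
strongest evidence, deterministic); self-loops are dropped at load (the
kernel adds its own diagonal mass); weights are preserved as given, never
thresholded. Genes without any interaction are removed (`drop_isolated`)
before normalization, which is undefined for them. `align_and_filter`
restricts everything to the genes interacting in *every* supplied network
(sorted lexicographically for a reproducible order) and discards modules with
fewer than 20 surviving members — too small for stable 5-fold estimates.

Two integration routes:

* `integrate_sum`: Laplacian-normalize each network, sum the matrices. The
  sum is treated as a raw adjacency downstream (re-normalized inside the
  kernel), keeping one recipe for single and integrated networks.
* `sw_integrate`: learns one non-negative weight per network by ridge
  regression of module co-membership on the networks' edge weights, jointly
  over all modules. The design samples all within-module pairs (target $+1$)
  plus an equal number of uniformly drawn non-member pairs per module
  (target $-1$); the full $|V|^2$ design would be intractable and the
  balanced sample preserves the regression's gradient direction. Negative
  solutions are clipped to zero and the system re-solved over the remaining
  networks. The sampling seed is an explicit argument.

## Evaluation protocol

`run_cv` performs 5-fold cross-validation repeated 5 times (both
configurable). *Stratified* means the module's positives are spread across
folds with counts differing by at most one; unlabeled genes are not
partitioned — they are candidates in every fold, since they carry no labels.
Test candidates are the held-out positives plus every gene never labeled
positive for that module; training positives are excluded because they
trivially rank on top and would inflate precision. Fold assignment is a
deterministic function of `(seed, repeat)`.

Metrics: precision at recall levels $0.1, \ldots, 1.0$ using the
step-function convention (smallest cutoff whose recall reaches the level; no
interpolation — the convention is a package choice), and AUC by the
tie-averaged rank-sum formulation (verified against brute-force pair counting
in the tests). `compare_methods` runs pairwise two-sided Wilcoxon signed-rank
tests on per-module mean AUCs — appropriate because AUCs of the same modules
under two methods are paired and far from normal — and tabulates mean AUC and
mean precision at 0.2 recall by module-cardinality group (20–100, 101–200,
201–300, 301+). When two methods tie on every module the signed-rank
statistic is undefined and $p = 1$ is reported by convention.

## The synthetic benchmark

`generate_network` draws a planted-partition graph: within-module pairs get
an edge with probability `p_in`, all other pairs with `p_out`. This is the
minimal structure that makes all five ranking methods distinguishable, since
each exploits neighbourhood co-membership differently. Defaults — 1000
genes, ten modules of 20–60 genes (the filter threshold upward), `p_in = 0.3`,
`p_out = 0.01`, constant unit weights — give within-module degrees of roughly
6–18 against a background degree of about 10: strong but not trivial signal,
on networks the same order of sparsity as curated functional networks. A gene
left isolated by the draw is re-wired to one uniformly chosen partner rather
than deleted, keeping `n_genes` exact; note this can attach a background gene
to a module, which matters in extreme corner cases (a `p_out = 0` clique is
recovered perfectly only if no background gene happens to re-wire into it).

`generate_network_pair` emulates networks built from complementary evidence:
one base draw, with a `divergence` fraction of the informative (within-module)
edges assigned exclusively to one of the two networks. At `divergence = 1`
each network carries half the signal and their normalized sum restores all of
it — the integration test bed.

What the generator does *not* emulate: heavy-tailed degree distributions,
weight heterogeneity correlated with evidence type, overlapping module
hierarchies, or annotation noise. Passing benchmarks here shows the methods
recover planted neighbourhood structure; it does not certify performance on
real curated networks.

## Numerical choices and limitations

* Symmetry is enforced to $10^{-9}$ at construction; kernels are checked PSD
  to an eigenvalue floor of $-10^{-8}$ in the tests.
* Dense `base` matrices throughout: the target scale (thousands of genes)
  multiplies in well under a second with any BLAS, and dense powers avoid
  fill-in bookkeeping. Memory is the binding constraint (a 20k-gene network
  would need ~3 GB per Gram matrix).
* Problem sizes in the test suite and acceptance script — 1000-gene
  networks, 10–20 seeded replicates, 5-fold CV with 1 repeat — were chosen
  as the smallest sizes at which the benchmark estimates stabilize
  (replicate standard errors well below the margins being asserted).
* At the default benchmark's signal strength the q = 2 and q = 3 kernels both
  saturate (mean AUC ≈ 0.9997); the degradation expected of longer walks on
  weaker signals is not expressed there.
* `alpha`, `k`, `a`, `q` are fixed globally; per-module tuning by internal
  CV is deliberately out of scope.
* Gene identifiers are case-sensitive opaque strings; no cross-nomenclature
  mapping is attempted.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
g <- generate_network(synthetic_config(n_genes = 300,
                                       module_sizes = c(25, 30, 40),
                                       seed = 7))
K <- q_step_rw_kernel(g$network, a = 2, q = 2)
res <- run_cv(g$network, g$modules, "SKNN", params = list(k = 27),
              folds = 5, repeats = 2, seed = 7, kernel = K)
mean_auc(res)
mean_precision_at(res, 0.2)

# rank all genes outside module M01 against it
sv <- score_knn(K, g$modules$modules$M01, k = 27)
head(rank_genes(sv))
```
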