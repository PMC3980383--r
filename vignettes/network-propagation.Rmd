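---
title: "Inferring drug-disease associations by heterogeneous network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring drug-disease associations by heterogeneous network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugprop)
```

## The model

Drugs act on protein targets; diseases perturb genes; perturbed genes sit in
functional modules of the protein-interaction network; and phenotypically
similar diseases tend to involve overlapping modules. `drugprop` encodes these
assumptions as one integrated network with three undirected weighted
*homo-networks* —

* **drug network** $W_d$: pairwise Tanimoto coefficients between hashed
  substructure fingerprints, $sim(x, x') = |x \cap x'| / |x \cup x'|$, in
  $[0, 1]$;
* **gene/protein network** $W_g$: each structural protein-interaction edge is
  weighted by disease-specific expression evidence,
  $W_g(g_i, g_j) = |R^d_{g_i g_j}| \cdot
  (|\bar E^d_{g_i} - \bar E^n_{g_i}| + |\bar E^d_{g_j} - \bar E^n_{g_j}|)$,
  where $R^d$ is the Pearson correlation across *case* samples and
  $\bar E^d, \bar E^n$ are within-class means — edges that are both
  co-expressed and differentially expressed under disease carry more weight;
* **phenotype network** $W_p$: raw text-mining phenotype-similarity scores
  pushed through a logistic transform $1/(1 + e^{c x + d})$ so that
  informative scores (raw $\ge 0.6$) approach 1 and non-informative scores
  (raw $\le 0.3$) approach 0

— connected by two binary bipartite *hetero-networks*: drug–target links
$W_{dg}$ and gene–phenotype links $W_{pg}$.

A disease-associated gene or drug target with no interaction partner would
absorb probability; such *sink nodes* instead receive a uniform small
connection $1/(n-1)$ to every other gene. Smoothing applies only to
hetero-referenced genes, so the remaining topology is untouched.

Every weight matrix $W$ is rescaled to a transition matrix
$S(i,j) = W(i,j) / \sqrt{D_r(i)\,D_c(j)}$ with $D_r$, $D_c$ the row and
column sums. For symmetric matrices this is the standard symmetric
normalization with spectral radius at most 1, so diffusion contracts.

## Propagation

On a single network a walker restarts at the initial distribution with
probability $1-\alpha$ and diffuses otherwise:
$p^t = (1-\alpha)\,p^0 + \alpha S\,p^{t-1}$, iterated until
$\lVert p^t - p^{t-1}\rVert_2 < 10^{-9}$. With $\alpha = 0$ the walker is
trapped at the initial nodes.

On the integrated network each homo-network $i$ with $k$ attached
hetero-networks additionally receives mass from its neighbors:

$$p_i^t = (1-\alpha_i)(1 - k\alpha_i)\,p_i^0
        + \alpha_i \sum_{j \ne i} S_{ij}\,p_j^0
        + \alpha_i S_i\,p_i^{t-1},$$

where the mixing coefficients $a_i = 1 - k\alpha_i$ and $b_{ij} = \alpha_i$
satisfy $a_i + \sum_j b_{ij} = 1$. A query starts with all probability on the
query phenotype (split uniformly over multiple query ids so the vector sums
to 1, which preserves the $a_i + \sum b_{ij} = 1$ probability rationale) and
zeros elsewhere. Inner loops iterate each homo-network to tolerance with the
neighbor vectors held fixed; the outer loop then hands every network's
converged vector to its neighbors and repeats until the concatenated state
moves less than the tolerance in L2.

**Outer-loop semantics.** Two readings of "use the converged probabilities as
the initial distribution" are possible. Replacing each network's *own*
restart vector as well makes the outer update a purely linear map
$x \mapsto Mx$: its only fixed point is $\mathbf{0}$, iterates either decay
to zero or — at the default diffusion parameters — grow without bound, so no
meaningful converged state exists. `drugprop` therefore updates only the
*neighbor* vectors $p_j^0$ between sweeps and keeps each network's restart
term anchored at the original initial distribution. The coupled system is
then affine with a unique fixed point (the package's oracle tests solve it
directly as one dense linear system and require agreement to $10^{-8}$), the
trapping limit at $\alpha = 0$ holds exactly, and updates are synchronous,
so results do not depend on the order in which the homo-networks are swept.
Inner solves use an exact direct linear solve below 2000 nodes — the same
fixed point the iteration reaches, at lower cost; iteration remains the
reference semantics and both paths are tested against each other.

**Coefficient modes.** The reported best diffusion setting is
$\alpha_d, \alpha_g, \alpha_p = 0.1, 0.7, 0.3$; with the gene network
attached to $k = 2$ hetero-networks this makes $a_g = 1 - 1.4 = -0.4$.
Whether the negative coefficient was clamped, renormalized or used as
written is not recoverable, so both behaviours are exposed:
`coefficient_mode = "literal"` (default) uses the formula as written —
because the gene network's own initial vector is zero for a phenotype query,
the negative coefficient multiplies a zero vector in the standard layout and
is harmless — and `"strict"` rejects any configuration with $a_i < 0$.
Negative entries that literal mode can produce in non-standard layouts are
clamped to zero at read-out with a logged count.

## Specificity scoring

Converged probabilities reflect network centrality as much as
disease-specific signal. The topology bias is measured by a *reference run*:
every structural protein-interaction edge weight is set to 1 (sink smoothing
re-applied) and the propagation repeated identically. Each node is then
standardized against the reference distribution,

$$Z_i(v) = \frac{P_i(v) - \mathrm{avg}(P_i^{ref})}{\mathrm{std}(P_i^{ref})},$$

with the population (divide-by-$N$) standard deviation, since the reference
set is the full distribution rather than a sample. Drugs with $Z > 2.33$
(one-tailed $p \approx 0.01$) are flagged significant. Note that with scalar
mean and standard deviation the *ranking* by $Z$ is identical to the ranking
by raw probability — the package asserts this as a regression guard — so the
reference run calibrates the significance filter rather than the order;
`mode = "nodewise"` additionally subtracts each node's own reference
probability, a per-node bias correction, without asserting which variant
underlies the published tables. Gene and phenotype Z-scores are reported too
(gene scores feed downstream functional-enrichment work, which is out of
scope here).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` (drug/gene/phenotype) | 0.1 / 0.7 / 0.3 | per-network diffusion strength, dimensionless in $[0,1)$; the default is the reported best AUC setting, recoverable with `parameter_sweep()` over the 125-cell grid $\{0.1,0.3,0.5,0.7,0.9\}^3$ |
| `tol` | $10^{-9}$ | L2 convergence threshold of inner and outer loops |
| `max_iter` | 10000 | iteration cap; exceeding it raises a convergence error identifying the level |
| `z_threshold` | 2.33 | one-tailed 1% significance cut on Z |
| logistic `c`, `d` | $-15$, $\ln 9999$ | phenotype-similarity calibration: $transform(0) = 10^{-4}$, midpoint $\approx 0.614$ between the informative and non-informative bands |

Extreme grid corners (e.g. all $\alpha = 0.9$) can make the coupled affine
system non-contractive; `parameter_sweep()` records such cells as `NA` with
the error message and continues.

## What the synthetic fixtures emulate

Real inputs (curated drug structures, text-mined phenotype similarities,
assembled interactome, tumor expression cohorts, curated benchmarks) cannot
ship with a package, so `generate_fixture()` plants a known signal with the
same statistical shape: a disease module of genes with correlated
differential expression (one shared latent factor produces the within-module
correlation — the simplest generative model of co-functioning co-expressed
genes), a denser interaction subgraph on the module, positive drugs that
share a fingerprint bit block and target module genes, a query phenotype
linked to module genes and phenotypically similar (raw $\ge 0.6$) to
phenotypes overlapping the module. Defaults: 60 drugs (10 positives), 200
genes (module of 20), 20 phenotypes, 10 case / 10 control samples, effect
size 2 noise-SD units, within-module correlation 0.6. A single seeded
generator threads through all draws, so fixtures are byte-reproducible from
one integer.

What passing tests show: the pipeline recovers planted module-mediated
drug–disease signal (median AUC $\ge 0.9$ across seeds, AUC monotone in
effect size) and stays at chance under the null (positives targeting
background genes, no expression signal). What they do not show: performance
on real data, whose marginal distributions (fingerprint density, interactome
degree sequence, expression heteroskedasticity, benchmark incompleteness)
the generator deliberately does not mimic.

```{r fixture-demo}
fx <- generate_fixture(fixture_spec(seed = 7))
state <- propagate_integrated(fx$network, fx$query)
ref <- reference_state(fx$network, fx$query)
ranking <- rank_drugs(state, ref)
head(ranking, 5)
roc_auc(setNames(ranking$z, ranking$drug_id), fx$benchmark)$auc
```

## Numerical and degenerate-input choices

* Zero row/column sums normalize to zero rows/columns rather than dividing
  by zero; an all-zero network simply passes no mass.
* A gene constant across case samples has an undefined correlation: its
  edges get weight 0 with a warning, keeping node sets stable; if such a
  gene is hetero-referenced and its whole row is zero it is sink-smoothed
  like any orphan.
* Duplicate undirected edges collapse to the maximum weight (similarity
  semantics); missing expression values drop the gene rather than impute.
* Ties in the drug ranking break lexicographically by drug id, and tied
  scores contribute 0.5 concordance to the AUC (Mann–Whitney convention), so
  all outputs are deterministic.
* Tanimoto similarity is 1 exactly when bit sets are equal, but no metric
  (triangle) property is relied on anywhere.

## Problem sizes

The shipped tests and the acceptance script run the full study condition
(60/200/20 nodes, 20 replicate seeds for the recovery and null medians, the
complete 125-cell sweep on a 20/60/8 fixture); these sizes give stable
medians while keeping a complete run in well under a minute on a laptop
core. Larger networks are limited mainly by the dense per-network linear
solves; above 2000 nodes the package falls back to the iterative inner loop.

## Known limitations

* Identifiers are opaque strings; database-specific id mapping and
  many-to-many UniProt/Entrez resolution must happen upstream.
* Only Tanimoto over hashed fingerprints is offered for chemical similarity;
  bit-vector similarity carries known molecule-size biases.
* Evaluation treats every non-benchmark drug as a negative, mirroring the
  usual protocol when no curated negative set exists; reported AUCs are
  therefore conservative when the benchmark is incomplete.
* The logistic calibration of phenotype similarities is a published default,
  not fitted to data; override `logistic_params()` when the raw score
  distribution differs.
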