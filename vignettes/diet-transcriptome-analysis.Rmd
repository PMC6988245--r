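---
title: "Diet-responsive transcriptome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-responsive transcriptome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietseq)
```

# Scope

`dietseq` implements an end-to-end analysis for bulk RNA-seq experiments
that contrast dietary treatments across tissues, built around the
factorial design it simulates by default: three diets (control `C`,
dietary restriction `DR`, high sugar `HS`) by three tissues (body `B`,
head `H`, ovary `O`) with six replicate batches, i.e. 54 samples and 18
per diet. The stages are

1. **Simulation** with planted ground truth (`simulate_counts()`),
2. **Preprocessing**: filtering, median-of-ratios size factors, a
   shifted-log transform, one surrogate variable, batch-effect removal,
3. **Differential expression**: per-gene negative-binomial GLMs compared
   by likelihood-ratio tests, with moderated log2 fold changes,
4. **Shared-reference concordance**: the package's centrepiece — a
   constrained-permutation test of whether two diets' fold changes
   against a shared reference trend together more than the
   ratio-versus-shared-denominator artifact alone would produce,
5. **Co-expression modules**: signed weighted network, topological
   overlap, average-linkage clustering with a static cut, eigengenes,
   merging, replicate-resampling robustness, and eigengene ANOVA,
6. **Gene-set statistics**: a two-sample t-test of per-gene fold changes
   per set, and Fisher-exact over-representation for module gene lists.

Every stage takes plain matrices/tibbles and returns tibbles (with
`tidy()`, `glance()` and `autoplot()` methods), so results chain with
ordinary tidyverse tooling.

# The generative model

The simulator draws counts
$$K_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\, \alpha\right),\qquad
\mu_{gj} = d_j \, 2^{\,b_g + t_{g,\mathrm{tissue}(j)} +
\delta_{g,\mathrm{diet}(j),\mathrm{tissue}(j)} + \beta_{\mathrm{batch}(j)}
+ \ell_g f_{m(g),j}}$$
with variance $\mu + \alpha\mu^2$. The components and their defaults:

| component | meaning | default |
|---|---|---|
| $b_g$ | baseline log2 abundance | $N(5, 2^2)$ |
| $t_{g,t}$ | per-gene tissue offset | $N(0, 2^2)$ — tissue dominates, as in real multi-tissue data |
| $\delta_{g,d,t}$ | planted diet effect | present in a fraction `pi_de = 0.2` of genes; magnitudes half-normal with sd `effect_size_sd = 0.5` ("subtle" diet effects) |
| $\beta_b$ | scalar batch offset | $N(0, 0.2^2)$, shared by all genes in a batch |
| $\ell_g f_{m,j}$ | module latent factor | loadings half-normal per `module_spec` |
| $d_j$ | depth multiplier | log-uniform on $[0.5, 2]$, the size-factor spread typical of such experiments |
| $\alpha$ | NB dispersion | 0.05, a conventional bulk RNA-seq value (no per-gene dispersion estimates were available to emulate) |

Three structural choices deserve justification:

* **Concordance is constructed, not sampled.** Among diet-affected
  genes, exactly `round(rho_concord * n_de)` get the same effect sign
  for `DR` and `HS` relative to `C`, the rest opposite signs, with
  magnitudes drawn independently. Recovery tests can therefore compare
  against an exact planted fraction.
* **Diet-by-tissue interaction preserves signs.** Each planted effect is
  multiplied per tissue by a log-normal factor
  ($e^{N(0,\,\texttt{interaction\_sd}^2)}$). An additive perturbation
  could flip the effect's sign in some tissue and silently break the
  exactness of the planted concordance fraction; the multiplicative form
  keeps both interaction and sign structure.
* **Module loadings are half-normal** ($|N(0, \mathrm{sd})|$), so
  within-module correlations are positive and a *signed* network can see
  them. Loadings vary across member genes, which realistically makes
  some members peripheral.

What the generator does *not* emulate: read-level sequencing artifacts
(GC/length bias, positional effects), isoform structure, correlated
dispersion-mean trends, and outlier samples. Tests passing on this
generator show the pipeline's statistics behave as designed under the
assumed NB factorial model; they are not evidence about robustness to
artifacts outside that model.

# Preprocessing

Size factors are plain median-of-ratios: $s_j = \mathrm{median}_g\,
K_{gj}/(\prod_{j'} K_{gj'})^{1/n}$ over genes positive in every sample.
Two filters mirror common practice and are exposed independently because
their interleaving at transcript versus gene level is a judgment call:
a variance filter (unbiased variance $\ge 1$ by default, applied to raw
counts) and a count filter (at least 10 reads in at least 2 samples).

The variance-stabilizing step is a **shifted log**,
$\log_2(K_{gj}/s_j + 1)$, rather than a model-based regularized log.
The shifted log preserves the monotone, variance-damping intent, is
exactly testable (closed form, scale-invariant), and avoids importing a
shrinkage procedure whose internals would dominate downstream behaviour.
Its provenance is recorded on the returned matrix.

Surrogate-variable estimation is deliberately minimal: per-gene least
squares on the protected factors (diet, tissue) plus batch, then the
first right singular vector of the residual matrix, centred, unit-norm,
sign-fixed by its largest element. One SV is returned because the
residual first PC is the deterministic, testable core of the idea; the
iterative reweighting of full surrogate-variable analysis is out of
scope. Batch and SV effects are then removed by `limma`'s joint
least-squares subtraction with the protected design shielded, so
protected group means survive to numerical tolerance.

# Differential expression

For each gene the package fits negative-binomial GLMs (log link, offsets
$\log s_j$, fixed gene-wise dispersion) for the nested scheme

* m1: `~ SV + batch + tissue`
* m2: `~ SV + batch + treatment`
* m3: `~ SV + batch + tissue + treatment`
* m4: `~ SV + batch + tissue + treatment + tissue:treatment`

and tests tissue (m3 vs m2), treatment (m3 vs m1) and interaction
(m4 vs m3) by likelihood-ratio chi-square, BH-adjusted per contrast at
FDR 0.05. With a single tissue the scheme collapses to
`~ SV + batch (+ treatment)` and only the treatment contrast is run.

Numerical choices:

* **Dispersion** is gene-wise method-of-moments on normalized counts,
  within-cell variances pooled with df weights:
  $\hat\alpha_g = \max(10^{-8}, (s_g^2 - \bar\mu_g)/\bar\mu_g^2)$. The
  floor prevents degenerate likelihoods for Poisson-like genes; no
  trended shrinkage is applied.
* **Fitting** uses IRLS (`glm.fit` with a fixed-theta NB family),
  gradient tolerance $10^{-8}$, 100 iterations. Non-converged genes get
  missing p-values, are excluded from BH, and are counted in
  `glance()`.
* **Fold changes** are moderated by a pseudocount:
  $\mathrm{LFC} = \log_2\{(\bar\mu_A + c)/(\bar\mu_B + c)\}$, $c = 0.5$
  by default. This is a deterministic, antisymmetric stand-in for
  prior-based shrinkage: it damps low-expression ratios and preserves
  ranking, and its closed form makes the concordance null exactly
  symmetric with the observed statistic. Fold changes are computed per
  tissue for every ordered diet pair, so each non-reference diet is
  expressed against every possible reference.

# The shared-reference concordance test

When two fold-change vectors share a reference group ($\mathrm{DR}$ vs
$\mathrm{C}$ and $\mathrm{HS}$ vs $\mathrm{C}$), they share the
denominator's sampling noise, so even exchangeable data produce a
positive correlation (asymptotically $r = 1/2$ with equal group sizes)
and a same-direction proportion above $1/2$ (about $2/3$ at $r = 1/2$).
Observed concordance must therefore be referred to a null that
*reproduces* the artifact.

The test statistics are the Pearson correlation of the two vectors and
the proportion of genes with matching nonzero fold-change signs (exact
zeros count only in the denominator — with continuous estimates they are
measure-zero, so the choice is inert). The null is built by **balanced
constrained permutation**: each pseudo-diet receives exactly two samples
drawn without replacement from every true diet, destroying any diet
effect while keeping group composition balanced — an unconstrained
shuffle of 6-sample groups would too often stack one true diet into a
pseudo-group and leak real signal into the null. With 6 replicates per
diet the labeled partition space has $(6!/(2!^3))^3 = 90^3 = 729{,}000$
elements per tissue; the default 100 permutations are drawn uniformly
with replacement from it. Null fold changes use the *same* moderated
procedure as the observed ones, and significance is the add-one
empirical p-value $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + M)$,
one-sided ("greater"), because the scientific hypothesis is *excess*
concordance. Every choice of reference diet is evaluated; the observed
statistics are independent of the permutation seed.

A practical note on power: the permutation distribution of the
proportion statistic has a between-permutation sd of roughly 0.02 at
$n = 6$ per diet, driven by the sample-level resampling rather than by
the number of genes. Subtle planted effects (half-normal magnitudes
around half a log2 unit) move the observed proportion only a few points
above the null mean, so per-dataset power at $\alpha = 0.05$ is moderate
(~70% in the package's own power study); strong effects
($|\mathrm{LFC}| = 2$) are detected essentially always. This mirrors the
method's behaviour on real data, where concordance p-values were modest
despite visibly correlated fold changes.

# Co-expression modules

The network is the signed adjacency $a_{ij} = ((1 + r_{ij})/2)^\beta$
with Pearson correlations and $\beta = 23$ by default; anti-correlated
genes get near-zero adjacency. Soft-threshold selection computes, per
candidate power, the whole-network connectivities and their scale-free
fit index. Bins are equal-occupancy, and the regression uses the log
frequency *density* (occupancy fraction over bin width) against log mean
connectivity — with equal-occupancy bins the raw occupancy is constant
by construction, so the density is what carries the shape of the degree
distribution. The smallest power reaching fit $\ge 0.90$ is chosen,
else the best-fitting power with a warning.

Topological overlap augments adjacency with shared-neighbour agreement,
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$
and `1 - TOM` feeds average-linkage hierarchical clustering. Modules are
obtained by a **static cut** at height 0.95 with minimum size 30; the
dynamic hybrid tree cut used by WGCNA-style pipelines is a package
heuristic with many internal parameters, while the static cut keeps the
identical height/min-size parameters, is exactly testable, and preserves
the pipeline's structure. Genes in clusters below the minimum size go to
the distinguished `"unassigned"` module (the grey-module convention).
A consequence worth knowing: under a static cut at 0.95 with
$\beta = 23$, modules whose true within-correlation is below roughly
0.75 have within-module TOM dissimilarity above the cut height and are
mathematically undetectable; the simulator's module studies therefore
plant tight modules (within-correlation near 0.9), the regime implied by
merged modules with eigengene correlation above 0.9.

Module eigengenes are first principal components of the gene-standardized
member submatrix, unit-norm across samples, oriented to correlate
non-negatively with the module's mean standardized profile (ties broken
by the largest element's sign). Modules whose eigengenes correlate
strictly above 0.9 merge greedily (highest pair first, eigengenes
recomputed after each merge); the strict inequality resolves an internal
ambiguity in the boundary convention, and the threshold is configurable.

**Robustness** re-runs the whole construction (including merging, with
the full-data $\beta$ reused rather than reselected) on 100 resampled
datasets keeping 4 of 6 replicates per diet-by-tissue cell. A resampled
module matches a full-data module when it contains at least 10% of that
module's genes (largest overlap wins, ties to the lexicographically
smallest label — a determinism tie-break). A gene's support is the
fraction of resamples in which it lands in a module matched to its own;
genes below 50% support are unassigned. Support is defined only for
genes the full-data network assigned: the resampling rule controls
spurious *retention*, while initial detection quality is a separate
question (measured by adjusted Rand index against planted labels).

Eigengene ANOVA fits `eigengene ~ diet * tissue` per module on the
balanced design (sequential and marginal sums of squares coincide under
balance, and the implementation refuses unbalanced designs rather than
silently reporting order-dependent tests), with BH adjustment across
modules within each term.

# Gene-set statistics

For pathway-style scoring, each set is compared to the background by a
Welch two-sample t-test of per-gene log2 fold changes (set versus all
background genes outside it), reporting the mean change
(set mean − rest mean), with BH adjustment across sets. The per-sample
meta-test layer of GAGE-style tooling is collapsed into this single
contrast-level test: the meta-test aggregates pairwise sample
comparisons internal to that package, whereas the reported quantities
(mean change, FDR) are properties of the collapsed test as well. The
default statistic is the fold change; the column is configurable. The
default two-sided alternative keeps direction visible through the sign
of the statistic. Minimum set size is 10 (conventional; nothing in the
emulated design pins it).

Module over-representation uses the one-sided hypergeometric tail
(Fisher exact) for the module-by-set 2×2 table over a background
universe, with Bonferroni adjustment across sets, matching the stricter
familywise convention usual for GO scans of module gene lists. Gene-set
collections are read and written as GMT; `make_synthetic_collection()`
builds random collections so the stage is testable without curated
databases.

# Orchestration and reproducibility

`run_all()` chains the stages, writing TSVs (each headed by a comment
line with the package version and a run id) plus a JSON manifest holding
the config snapshot, per-stage seeds, timestamps and output digests.
All stage seeds derive deterministically from the global seed and the
stage name, so any stage can be reproduced in isolation; a failing stage
writes a partial manifest recording where and why. Configuration is a
strict nested list: unknown keys error before any compute.

# Problem sizes used by the test suite

The package's own checks run at deliberately modest scales chosen to
exercise every code path with stable statistics: null and power studies
of the concordance test at 500–3000 genes and 100 permutations over up
to 50 datasets; differential-expression calibration and recovery at
2000 genes and 6 replicates per diet; module recovery at 500 genes
(five planted 50-gene modules plus 250 noise genes) with 100 resampled
networks; ANOVA calibration over 200 null eigengenes. Exact oracles
(enumeration, brute-force step-up, triple-loop TOM, grid-search
likelihood) back the deterministic primitives at small sizes.

# Known limitations

* The shifted log, residual-PCA surrogate variable, pseudocount fold
  changes and static tree cut are deliberate, documented simplifications
  of heavier model-internal procedures; each preserves the role of its
  counterpart but not its exact output.
* Method-of-moments dispersions are noisy at few replicates and carry no
  trended shrinkage, making the LRT slightly conservative or liberal
  gene-by-gene; calibration holds in aggregate.
* The permutation concordance test's power is bounded by the
  between-permutation variability at small group sizes (see above).
* The module pipeline targets a few thousand genes; no block-wise
  decomposition is provided for much larger matrices.
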