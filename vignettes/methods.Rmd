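---
title: "Methods: expression-constrained fluxes and biased similarity network fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained fluxes and biased similarity network fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseflux)
```

`fuseflux` turns a gene-expression compendium plus a genome-scale
metabolic model into a fused multi-omic network of growth conditions, and
then explains the network's cluster structure in terms of fluxes. This
vignette documents the model, its assumptions, the tunable parameters, the
synthetic generators used for validation, and the numerical choices made
where the design was genuinely open.

## 1. From expression to condition-specific flux distributions

### Gene-set expression

A reaction is available when its gene-protein-reaction (GPR) boolean rule
is satisfied. We collapse per-gene expression ratios θ (dimensionless,
1 = the wild-type/reference level) onto a per-reaction gene-set value Θ by
structural recursion: a leaf contributes θ(g), an AND node (enzyme
complex, all subunits needed) the minimum of its children, an OR node
(isozymes, any suffices) the maximum. The same recursion applied to
per-gene variances across conditions yields the gene-set variance σ².
Genes absent from a condition's profile contribute the neutral value 1; a
gene-set variance that ends up missing or below `sigma2_floor` is floored.

### The φ bound map

Expression modulates each reaction's default bounds multiplicatively:

$$\varphi(\Theta) = \Big[1 + \frac{\gamma}{\sigma^2}\,|\log \Theta|\Big]^{\mathrm{sgn}(\Theta-1)},
\qquad \varphi(1)=1,\ \varphi(0)=0 .$$

Over-expression relaxes bounds sub-linearly (logarithmically), matching
the observed saturation of protein synthesis at high mRNA abundance;
under-expression tightens them symmetrically, and the map degrades
gracefully to the boolean on/off limit as Θ → 0. The inverse-variance
factor encodes the prior that genes with low expression variance across
many conditions are tightly regulated, hence metabolically important, so
their changes should move the model more. Two identities are useful for
testing and intuition: φ(Θ)·φ(1/Θ) = 1 (a 2-fold induction and a 2-fold
repression cancel exactly), and φ is strictly increasing in Θ.

Parameters (`map_parameters()`):

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | weight of the inverse-variance prior (dimensionless); larger values let expression act more strongly, especially on stable genes |
| `log_base` | e | base of the logarithm; the map is advertised as adjustable, and base only rescales γ/σ² jointly |
| `sigma2_floor` | 1e-6 | variance floor; prevents division by zero for genes constant across the compendium |

Because γ/σ² multiplies |log Θ|, genes with very small across-condition
variance have steep φ responses. This is intended behaviour, but it means
technical noise on an otherwise constant gene is amplified; σ² is
therefore always computed on the raw (pre-discretization) compendium over
*all* conditions, never per condition subset.

### Lexicographic (trilevel) FBA

Each condition is solved as a nested sequence of 1–3 linear programs over
the steady-state polytope {v : Av = 0, Vᵐⁱⁿφ ≤ v ≤ Vᵐᵃˣφ}: the first
objective (e.g. biomass, h⁻¹) is maximized, fixed, and the next objective
(e.g. a secretion flux, mmol h⁻¹ gDW⁻¹) is maximized over the optimal
face. We read the nested max operators of the trilevel program
lexicographically, with the innermost objective as the highest priority —
the outer levels optimize over the inner optimal sets. Fixing uses the
constraint cᵀv ≥ z* − `fix_tol`·max(1, |z*|) with `fix_tol = 1e-9`: a pure
equality can make the optimal face numerically empty, while a loose
tolerance leaks into later objectives, so the default is tight but
nonzero. On degenerate final faces only the objective values are
reproducible; the returned vertex is solver-dependent by nature.

The LPs are solved by an internal dense two-phase primal simplex with
Bland's anti-cycling rule. Flux polytopes are heavily degenerate (many
bounds sit exactly at 0), which defeats naive pivoting heuristics; Bland's
rule guarantees termination, and at the problem sizes this package targets
(tens of reactions after per-condition reduction) the dense tableau is
fast. The test suite checks the solver against exhaustive vertex
enumeration of the feasible polytope on every toy model and on random
networks.

## 2. Building and fusing the condition multiplex

### Per-layer preprocessing

For each omic layer (conditions × features): drop features with fewer
than 10 % known and finite values (strict "less than": exactly 10 % is
kept); impute remaining missing entries with the column median; replace
each value by its 20-quantile index within its feature (average ranks for
ties, mapped with ⌈rank/n·20⌉ — the tie rule and the ceiling mapping are
this package's choice). The quantile step makes the pipeline invariant to
monotone transforms of any feature and tames the very heavy tails
(outliers are deliberately kept: all-or-nothing flux responses are
biologically meaningful bistability, not artifacts).

### Similarity kernels and a numerical caveat

Distances between condition rows are Euclidean. Two kernels are provided:
the plain negative-squared-exponential P = e^(−d²) and the scaled kernel
W = exp(−d²/(μ·ε)) with the local bandwidth ε averaging the K-nearest
distances of both endpoints. The plain kernel on raw quantile distances
underflows at realistic dimensionality (d² in the hundreds-to-thousands,
so every off-diagonal entry is numerically 0 next to the unit diagonal),
and even the scaled kernel's exponent grows linearly with the distance
scale. `condition_layer()` therefore rescales distances by their median
positive value before either kernel (default `rescale = TRUE`); for the
scaled kernel this is exactly a bandwidth change (rescaling distances by c
maps W to W^c), and it puts typical exponents at order 1. The scaled
kernel is the default because its local bandwidth adapts to density
differences between condition groups.

### Status matrices, local kernels, and the biased update

Each layer's similarity matrix W is normalized into a row-stochastic
status matrix P₀. The default is the robust form — off-diagonal entries
W(i,j)/(2Σ_{k≠i}W(i,k)), diagonal ½ — which keeps half of every row's mass
on the node itself and is insensitive to the diagonal's scale. The local
kernel S keeps each row's K most similar entries (self always included,
counted within K; ties broken by column order) and row-normalizes.

The fusion update, per layer v, diffuses the bias-weighted mean of the
*other* layers through the layer's own local kernel:

$$P^{(v)} \leftarrow S^{(v)}\,
\frac{\sum_{k\neq v} b_k P^{(k)}}{\sum_{k\neq v} b_k}\,
(S^{(v)})^{\top}.$$

Design notes, in decreasing order of consequence:

* **Where the bias acts.** For m = 2 layers the weighted mean over the
  single other layer cancels b entirely, so a 2:1 phenotype:transcriptome
  bias would be a no-op if it only entered the update. The bias is
  therefore also applied in the final aggregate Σ bᵥP⁽ᵛ⁾/Σ bᵥ (and the
  update retains it for m > 2, where it does matter). `fuse()` exposes
  `bias_in_update` so either reading can be used; the aggregate weighting
  is always applied.
* **Normalization of the weighted mean.** The update uses the weighted
  *mean* (denominator Σ_{k≠v}bₖ), which reduces exactly to the unweighted
  mean over m−1 layers when all biases are equal. A variant that divides
  additionally by m−1 would shrink the status matrices by that factor each
  iteration for m > 2 and break the equal-bias reduction; the weighted
  mean is the self-consistent choice and coincides with the biased formula
  at m = 2, the configuration the bias was designed for.
* **Per-iteration conditioning.** After each update the matrix is
  symmetrized ((P+Pᵀ)/2, exact because S·M·Sᵀ of a symmetric M is already
  symmetric up to the asymmetry inherited from the previous
  renormalization) and then renormalized with the robust form. Without
  these steps the iteration drifts numerically. The order (symmetrize,
  then renormalize) makes every row sum exactly 1 after each iteration at
  the cost of a small (~1e-2) transient asymmetry, which the next
  iteration's symmetrization absorbs; the final fused matrix is
  symmetrized exactly.
* **Convergence.** The change scalar cₙ is the mean relative Frobenius
  change across layers. Iteration stops when cₙ < `tol1` and
  |cₙ−cₙ₋₁| < `tol2` (both 1e-6 by default — the first and second
  discrete derivatives of the trace), or at `max_iter = 20`. If cₙ rises
  for 5 consecutive iterations the run is flagged divergent and the
  partial result returned rather than discarded.
* **Degenerate inputs.** A node whose off-diagonal similarities are all
  zero makes the robust normalization undefined; this is reported as an
  error naming the node rather than silently regularized.

### Clustering and attribution

Spectral clustering embeds the fused network with the top k eigenvectors
of D^(−1/2)WD^(−1/2), row-normalizes them, and runs k-means with 20
restarts under an explicit seed; the cluster count k is a user decision
(automatic selection is out of scope). Cluster attribution fits a CART
classification tree (Gini impurity, no surrogates) on the flux matrix and
prunes it to at most `max_rules` splits via the complexity table — "two
rules" is the default because two univariate thresholds suffice to
separate three ordered flux regimes. Importances are the tree's
improvement scores normalized to sum to 1. Bootstrap validation refits the
tree on `n_resamples` draws of 80 % of the conditions without replacement;
a feature's stability is the fraction of resamples in which it is used by
a split, and the per-resample top-importance feature is recorded
separately. Ties between features that split equally well are resolved by
column order — deterministic, but worth remembering when features are
exact linear combinations of each other, as fluxes in small networks often
are.

## 3. What the synthetic generators emulate — and what they do not

`planted_compendium()` draws conditions around cluster-specific mean
expression profiles with log-normal multiplicative noise (ratio scale
centred at 1; log-normal because the scale is multiplicative and the bound
map is logarithmic). Defaults: 90 conditions, 50 genes, 3 equal clusters,
effect size 1 (cluster means spread over e^±0.7 ≈ 0.5×–2×wild type),
noise sd 0.1 on the log scale. The cluster pattern is planted on the
genes of the toy model's uptake→conversion pathway — a deliberate choice:
real condition shifts scale coordinated pathways rather than single
enzymes, and planting the signal on a pathway keeps the planted genes'
across-condition variance in the range where the inverse-variance map
responds smoothly instead of amplifying residual noise on near-constant
genes. Half of the filler genes carry a permuted version of the cluster
pattern (so the transcriptomic layer is informative on its own); the rest
are pure noise. The sizes keep the full pipeline — 90 trilevel LP solves,
two layers, fusion, clustering, 100 bootstrap refits — under a couple of
minutes on one CPU.

`planted_multiplex()` generates block similarity matrices (within 0.8,
between 0.2 by default) with symmetrized, clipped Gaussian noise per
layer — the classic planted-partition setting used to test fusion
recovery independently of the metabolic machinery.

What passing these tests shows: the algebra of the map, the LP stack, and
the fusion/attribution machinery recover structure whose generative form
they match. What it does not show: performance on real compendia, where
cluster structure is not block-shaped, noise is not log-normal,
annotation errors exist, expression and flux layers can disagree
systematically, and the genome-scale model itself is imperfect — the very
situation the layer bias is meant to express.

## 4. Known limitations

* The dense simplex targets desk-scale and moderate models; genome-scale
  reconstructions with thousands of reactions would need a sparse LP
  backend behind the same `fba()` surface.
* σ² flooring and the neutral-value policy for missing genes are
  pragmatic defaults; compendia with many missing genes deserve explicit
  sensitivity checks.
* The SBML reader covers Level 3 core plus the fbc gene-association and
  flux-bound constructs used by current reconstructions; it is not a
  general SBML implementation (no kinetic laws, no groups).
* Attribution on small networks is limited by flux coupling: linearly
  dependent fluxes share importance arbitrarily (column-order ties), so
  the planted "discriminative set" should be read as a pathway, not a
  single reaction.
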