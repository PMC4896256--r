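# fuseflux

Multi-omic condition networks from expression-constrained metabolic models.

## What this package is for

Compendia of microbial growth conditions are usually compared on one omic
at a time — typically the transcriptome. `fuseflux` compares conditions on
two coupled levels at once: the measured gene expression profile and the
metabolic flux phenotype that profile implies under a genome-scale
constraint-based model. Conditions become nodes of a two-layer multiplex
network (transcriptomic similarity, fluxomic similarity); the layers are
fused into a single network with a bias-weighted similarity network fusion
(SNF) algorithm; and the fused network is clustered and explained in terms
of the fluxes that drive the clusters. The package is aimed at systems
biologists working with expression compendia and genome-scale metabolic
reconstructions.

## The model at the core

**From genes to reaction bounds.** Each reaction *i* carries a
gene-protein-reaction (GPR) boolean rule; per-gene expression ratios θ
(1 = wild type) collapse onto a gene-set value Θᵢ with min over AND
(enzyme complexes) and max over OR (isozymes). Θᵢ then scales the
reaction's flux bounds through the logarithmic, variance-weighted map

  φ(Θᵢ) = [1 + (γ/σᵢ²)·|log Θᵢ|]^sgn(Θᵢ−1),  φ(1) = 1,

where σᵢ² is the gene set's variance across all conditions (low variance ⇒
the gene is treated as important, so its expression moves the bounds more)
and γ weights that prior. The effective bounds are
Vᵢᵐⁱⁿ·φ(Θᵢ) ≤ vᵢ ≤ Vᵢᵐᵃˣ·φ(Θᵢ).

**From bounds to fluxes.** Each condition is solved as a lexicographic
(up to trilevel) flux-balance program: maximize the first objective subject
to Av = 0 and the φ-scaled bounds, fix it, maximize the next objective on
the optimal face, and so on (e.g. biomass, then acetate). Objective-space
point clouds across conditions support Pareto trade-off extraction
(`pareto_front()`).

**From fluxes to a fused condition network.** Per layer, features are
filtered (< 10 % finite dropped), replaced by their 20-quantile index
(robust to the heavy tails of flux data), converted to Euclidean distances
and then to similarities with an exponential kernel. SNF normalizes each
layer into a row-stochastic status matrix P (robust form: diagonal ½) and a
K-nearest-neighbour kernel S, then iterates the bias-weighted
cross-diffusion

  P⁽ᵛ⁾ ← S⁽ᵛ⁾ · (Σₖ≠ᵥ bₖ P⁽ᵏ⁾ / Σₖ≠ᵥ bₖ) · S⁽ᵛ⁾ᵀ

until the first and second discrete derivatives of the change scalar
vanish. The per-layer bias b (e.g. 2:1 phenotype:transcriptome) expresses
confidence in each omic; for two layers it provably cancels inside the
update, so it is also applied in the final aggregate Σ bᵥP⁽ᵛ⁾/Σ bᵥ.

**From the fused network to biology.** Spectral clustering (normalized
Laplacian + k-means) groups the conditions; a CART tree limited to two
rules attributes the clusters to dominant fluxes, validated by bootstrap
(80 % resamples, stability = how often a flux is rediscovered).

## Worked example

Synthetic desk-scale run: a 6-reaction toy model, a 90-condition
compendium with three planted condition clusters driven by the
uptake/conversion pathway, fused with a 2:1 fluxomic:transcriptomic bias.

```r
library(fuseflux)

model <- toy_model("branch")
model
#> <metabolic_model> 3 metabolites x 6 reactions, 8 genes, 6 GPR rules

comp <- planted_compendium(fixture_spec(seed = 1), model)
comp
#> <expression_compendium> 90 conditions x 50 genes (100.0% finite)

out <- fuse_conditions(model, comp, objectives = c("biomass", "product"),
                       K = 30, bias = c(2, 1), k_clusters = 3, seed = 1)
out$fusion
#> <fusion_result> 90 nodes; 17 iteration(s); converged
out$clusters
#> <cluster_assignment> k = 3; sizes: 30, 30, 30
out$attribution
#> <attribution_report> 2 rule(s); training accuracy 1.000
#>   importance: uptake=1.00

mclust::adjustedRandIndex(out$clusters$labels, comp$metadata$cluster)
#> [1] 1
round(tapply(out$flux$values[, "uptake"], comp$metadata$cluster, mean), 2)
#>     1     2     3
#>  3.76 10.22 26.63
```

The three planted clusters are recovered exactly (adjusted Rand index 1),
and the two-rule tree identifies the uptake flux — the reaction whose
pathway the generator perturbed — as the cluster driver, splitting the
three uptake regimes (≈ 3.8 / 10.2 / 26.6 mmol h⁻¹ gDW⁻¹).

A command-line wrapper with the same steps
(`map-conditions`, `fuse`, `cluster`, `attribute`, `simulate-fixtures`)
is installed at `system.file("cli/fuseflux.R", package = "fuseflux")`.

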