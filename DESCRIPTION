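Package: fuseflux
Title: Multi-Omic Condition Networks from Expression-Constrained Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps condition-specific gene expression onto genome-scale
    metabolic models through a variance-weighted logarithmic bound map and
    lexicographic (trilevel) flux-balance analysis, builds transcriptomic and
    fluxomic condition-similarity layers, fuses them with a bias-weighted
    similarity-network-fusion algorithm, and attributes the resulting
    condition clusters to dominant fluxes via recursive partitioning with
    bootstrap validation. Includes readers for SBML (Level 3, fbc package)
    and a light JSON model dialect, gene-protein-reaction (GPR) boolean rule
    parsing and evaluation, Pareto trade-off extraction in objective space,
    and synthetic fixture generators with planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
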