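#' Specification of a synthetic fixture
#'
#' Bundles the sizes, effect size and noise level of the synthetic
#' generators. Defaults (90 conditions, 50 genes, 3 clusters) emulate, at
#' desk scale, a compendium of growth conditions with planted condition
#' clusters.
#'
#' @param seed integer seed; every generator consuming the spec is fully
#'   deterministic given it.
#' @param n_conditions,n_genes,n_clusters sizes.
#' @param effect_size mean within-vs-between cluster separation on the
#'   log-expression scale (0 = no recoverable structure).
#' @param noise_sd standard deviation of the log-normal multiplicative
#'   noise (0 = identical rows within a cluster).
#' @param block_sizes cluster sizes, summing to `n_conditions`
#'   (default: as equal as possible).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_conditions = 90, n_genes = 50,
                         n_clusters = 3, effect_size = 1, noise_sd = 0.1,
                         block_sizes = NULL) {
  if (is.null(block_sizes)) {
    base <- n_conditions %/% n_clusters
    block_sizes <- rep(base, n_clusters)
    extra <- n_conditions - sum(block_sizes)
    if (extra > 0) block_sizes[seq_len(extra)] <- block_sizes[seq_len(extra)] + 1
  }
  if (sum(block_sizes) != n_conditions)
    stop("block sizes must sum to n_conditions", call. = FALSE)
  if (any(c(n_conditions, n_genes, n_clusters, block_sizes) <= 0) ||
      effect_size < 0 || noise_sd < 0)
    stop("fixture sizes must be positive; effect_size and noise_sd non-negative",
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_conditions = n_conditions,
                 n_genes = n_genes, n_clusters = n_clusters,
                 effect_size = effect_size, noise_sd = noise_sd,
                 block_sizes = block_sizes),
            class = "fixture_spec")
}

#' Toy metabolic models with known optima
#'
#' Two small networks whose LP optima are known in closed form (and
#' verified by exhaustive vertex enumeration in the test suite):
#' \describe{
#'   \item{`"chain"`}{1 metabolite, 3 reactions: `uptake` (capacity 10)
#'     feeds `M`, which `biomass` and `product` drain. Max biomass = 10;
#'     lexicographic `[biomass, product]` = (10, 0).}
#'   \item{`"branch"`}{adds a conversion step `conv` (`M -> B`, capacity 6)
#'     so the lexicographic levels interact: biomass drains `B`, product
#'     drains `M` directly. Lexicographic `[biomass, product]` = (6, 4).
#'     A second independent pathway (`uptake2 -> N -> sink`, capacity 5)
#'     carries no cluster signal and serves as a non-discriminative flux.}
#' }
#' All GPRs are single genes or 2-gene AND/OR rules; the `uptake`/`conv`
#' pathway genes are the levers the planted compendium perturbs.
#'
#' @param variant `"chain"` or `"branch"`.
#' @return a `metabolic_model`.
#' @export
toy_model <- function(variant = c("chain", "branch")) {
  variant <- match.arg(variant)
  if (variant == "chain") {
    S <- matrix(c(1, -1, -1), 1,
                dimnames = list("M", c("uptake", "biomass", "product")))
    return(metabolic_model(S, c(0, 0, 0), c(10, 1000, 1000),
                           gpr = list(uptake = "gU",
                                      biomass = "gB1 AND gB2",
                                      product = "gP1 OR gP2")))
  }
  rxns <- c("uptake", "conv", "biomass", "product", "uptake2", "sink")
  S <- matrix(0, 3, 6, dimnames = list(c("M", "B", "N"), rxns))
  S["M", "uptake"] <- 1
  S["M", "conv"] <- -1; S["B", "conv"] <- 1
  S["B", "biomass"] <- -1
  S["M", "product"] <- -1
  S["N", "uptake2"] <- 1
  S["N", "sink"] <- -1
  metabolic_model(S,
                  lower_bounds = rep(0, 6),
                  upper_bounds = c(10, 6, 1000, 1000, 5, 1000),
                  gpr = list(uptake = "gU",
                             conv = "gC1 OR gC2",
                             biomass = "gB",
                             product = "gP1 AND gP2",
                             uptake2 = "gS1",
                             sink = "gS2"))
}

#' Generate an expression compendium with planted condition clusters
#'
#' Conditions are drawn around cluster-specific mean profiles with
#' log-normal multiplicative noise on the ratio scale (centred at 1 = wild
#' type). The genes of the model's `uptake` and `conv` reactions (the
#' planted pathway) receive designed cluster multipliers
#' `exp(effect_size * s_c)` with `s_c` spread evenly in `[-0.7, 0.7]` (so,
#' at the default effect size, roughly 0.5x / 1x / 2x wild type for three
#' clusters). Perturbing a pathway rather than a single enzyme mirrors how
#' growth conditions shift coordinated sets of fluxes, and it keeps the
#' planted genes' across-condition variance in a realistic range for the
#' inverse-variance bound map; the uptake flux is the planted
#' discriminative flux. Half of the filler genes are informative with a
#' randomly permuted version of the same pattern, so the transcriptomic
#' layer carries the cluster signal too; the rest are pure noise.
#'
#' @param spec a [fixture_spec()].
#' @param model a `metabolic_model` whose GPR genes must fit within
#'   `spec$n_genes`.
#' @return an `expression_compendium`; `metadata$cluster` holds the ground
#'   truth and the `planted` attribute records the perturbed gene and the
#'   reactions whose gene set contains it.
#' @export
planted_compendium <- function(spec, model) {
  stopifnot(inherits(spec, "fixture_spec"))
  model_genes <- model$gene_ids
  if (length(model_genes) > spec$n_genes)
    stop("n_genes is smaller than the model's gene set", call. = FALSE)
  n_fill <- spec$n_genes - length(model_genes)
  genes <- c(model_genes,
             if (n_fill > 0) sprintf("fill%03d", seq_len(n_fill)))
  clusters <- rep(seq_len(spec$n_clusters), spec$block_sizes)
  cond_ids <- sprintf("cond%03d", seq_len(spec$n_conditions))

  pathway <- intersect(c("uptake", "conv"), names(model$gpr))
  if (!length(pathway)) pathway <- names(model$gpr)[1]
  planted_genes <- unique(unlist(lapply(model$gpr[pathway], gpr_genes)))
  planted_rxns <- names(Filter(function(g) any(planted_genes %in% gpr_genes(g)),
                               model$gpr))

  pattern <- seq(-0.7, 0.7, length.out = spec$n_clusters)
  mu <- matrix(0, spec$n_clusters, length(genes),
               dimnames = list(NULL, genes))
  mu[, planted_genes] <- spec$effect_size * pattern

  values <- with_seed(spec$seed, {
    if (n_fill > 0) {
      informative <- sprintf("fill%03d", seq_len(ceiling(n_fill / 2)))
      for (g in informative)
        mu[, g] <- spec$effect_size * sample(pattern)
    }
    noise <- matrix(stats::rnorm(spec$n_conditions * length(genes),
                                 sd = spec$noise_sd),
                    spec$n_conditions, length(genes))
    exp(mu[clusters, , drop = FALSE] + noise)
  })
  dimnames(values) <- list(cond_ids, genes)
  out <- expression_compendium(values,
                               metadata = data.frame(cluster = clusters,
                                                     row.names = cond_ids))
  attr(out, "planted") <- list(genes = planted_genes, reactions = planted_rxns)
  out
}

#' Generate a multiplex network with a planted partition
#'
#' Each layer is a block similarity matrix — `within_sim` on the diagonal
#' blocks, `between_sim` elsewhere — plus symmetrized Gaussian noise,
#' truncated (clipped) to `[0, 1]`. Layers differ only in their noise
#' realization (sub-seeds `seed`, `seed + 1`, ...).
#'
#' @param spec a [fixture_spec()]; supplies block sizes and `noise_sd`.
#' @param n_layers number of layers (default 2).
#' @param within_sim,between_sim block similarities,
#'   `0 <= between_sim < within_sim <= 1`.
#' @param K neighbourhood size passed to [multiplex_network()]
#'   (default `n/3`).
#' @param bias per-layer bias (default equal).
#' @return a `multiplex_network`; ground-truth labels are in the
#'   `planted_labels` attribute.
#' @export
planted_multiplex <- function(spec, n_layers = 2, within_sim = 0.8,
                              between_sim = 0.2,
                              K = max(2L, ceiling(spec$n_conditions / 3)),
                              bias = rep(1, n_layers)) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!(between_sim >= 0 && between_sim < within_sim && within_sim <= 1))
    stop("require 0 <= between_sim < within_sim <= 1", call. = FALSE)
  labels <- rep(seq_len(spec$n_clusters), spec$block_sizes)
  n <- spec$n_conditions
  ids <- sprintf("cond%03d", seq_len(n))
  base <- ifelse(outer(labels, labels, "=="), within_sim, between_sim)
  layers <- lapply(seq_len(n_layers), function(l) {
    W <- with_seed(spec$seed + l - 1L, {
      E <- matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
      base + (E + t(E)) / 2
    })
    W <- pmin(pmax(W, 0), 1)
    dimnames(W) <- list(ids, ids)
    W
  })
  net <- multiplex_network(layers, bias = bias, K = K)
  attr(net, "planted_labels") <- labels
  net
}
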