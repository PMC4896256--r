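#' End-to-end multi-omic condition fusion
#'
#' Runs the whole pipeline on a model plus expression compendium: map every
#' condition through the \eqn{\varphi} bound map and the lexicographic LP
#' ([map_compendium()]), build one similarity layer per omic
#' (fluxomic from the flux matrix, transcriptomic from the expression
#' matrix; see [condition_layer()]), fuse the two-layer multiplex
#' ([fuse()]), spectrally cluster the fused network and attribute the
#' clusters to dominant fluxes ([attribute_clusters()]).
#'
#' Conditions whose LP solve failed are dropped from both layers (with a
#' message) before network construction.
#'
#' @param model a `metabolic_model`.
#' @param compendium an `expression_compendium`.
#' @param objectives objectives for [lexicographic_fba()], highest priority
#'   first.
#' @param params a [map_parameters()] object.
#' @param K fusion neighbourhood size (default `n/3`).
#' @param bias two-entry bias, fluxomic layer first (default `c(2, 1)`:
#'   phenotype trusted twice as much as transcriptome).
#' @param k_clusters number of condition clusters (default 3).
#' @param seed integer seed for clustering and attribution.
#' @param max_rules tree size limit for the attribution step.
#' @param kernel,mu similarity kernel settings for [condition_layer()].
#' @return list with `flux` (`condition_flux_matrix`), `layers` (named list
#'   of similarity matrices), `fusion` (`fusion_result`), `clusters`
#'   (`cluster_assignment`), and `attribution` (`attribution_report`).
#' @export
fuse_conditions <- function(model, compendium, objectives,
                            params = map_parameters(),
                            K = max(2L, ceiling(nrow(compendium$values) / 3)),
                            bias = c(2, 1), k_clusters = 3, seed = 1L,
                            max_rules = 2, kernel = "scaled", mu = 0.5) {
  flux <- map_compendium(model, compendium, params, objectives)
  ok <- flux$status == "optimal"
  if (!all(ok))
    message(sum(!ok), " condition(s) dropped after LP failure: ",
            paste(utils::head(names(which(!ok)), 5), collapse = ", "))
  flux_vals <- flux$values[ok, , drop = FALSE]
  expr_vals <- compendium$values[ok, , drop = FALSE]
  layers <- list(
    fluxomic = condition_layer(flux_vals, kernel = kernel, mu = mu, K = K),
    transcriptomic = condition_layer(expr_vals, kernel = kernel, mu = mu, K = K))
  net <- multiplex_network(layers, bias = bias, K = K)
  fusion <- fuse(net)
  clusters <- spectral_cluster(fusion$fused, k_clusters, seed = seed)
  attribution <- attribute_clusters(flux_vals, clusters, max_rules = max_rules,
                                    seed = seed)
  list(flux = flux, layers = layers, fusion = fusion, clusters = clusters,
       attribution = attribution)
}
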