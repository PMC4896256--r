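#' Map one condition's expression onto the model and solve the trilevel LP
#'
#' Computes the condition's gene-set profile (\eqn{\Theta_i} per reaction;
#' \eqn{\sigma_i^2} across the whole compendium), scales the flux bounds
#' through the \eqn{\varphi} map and solves the lexicographic program. An LP
#' failure is returned as a marked failure (status in the result), not an
#' error, so compendium-wide mapping can continue.
#'
#' @param model a `metabolic_model` with GPR rules.
#' @param compendium an `expression_compendium`.
#' @param condition_id condition to map.
#' @param params a [map_parameters()] object.
#' @param objectives objectives for [lexicographic_fba()].
#' @param fix_tol fixing tolerance for [lexicographic_fba()].
#' @return a `flux_distribution` (status `"optimal"` or `"failed"` with the
#'   failure reason in the `reason` attribute).
#' @export
map_condition <- function(model, compendium, condition_id,
                          params = map_parameters(), objectives,
                          fix_tol = 1e-9) {
  profile <- gene_set_profile(model, compendium, condition_id, params)
  bounded <- condition_bounds(model, profile, params)
  tryCatch(
    lexicographic_fba(bounded, objectives, fix_tol),
    error = function(e) {
      n_levels <- if (is.character(objectives)) length(objectives) else length(objectives)
      structure(
        new_flux_distribution(model, rep(NA_real_, length(model$reaction_ids)),
                              rep(NA_real_, n_levels), "failed"),
        reason = conditionMessage(e))
    })
}

#' Map a whole compendium to per-condition flux profiles
#'
#' Runs [map_condition()] for every condition. Solves are independent
#' across conditions (the order does not influence any result), so the
#' output is permutation-equivariant in conditions.
#'
#' @inheritParams map_condition
#' @return an object of class `condition_flux_matrix`: list with `values`
#'   (conditions \eqn{\times} reactions flux matrix; failed rows are `NA`),
#'   `objective_values` (conditions \eqn{\times} levels), and `status`
#'   (named character; failures carry their reason in the `failures`
#'   attribute).
#' @export
map_compendium <- function(model, compendium, params = map_parameters(),
                           objectives, fix_tol = 1e-9) {
  ids <- rownames(compendium$values)
  n_levels <- if (is.character(objectives)) length(objectives) else length(objectives)
  values <- matrix(NA_real_, length(ids), length(model$reaction_ids),
                   dimnames = list(ids, model$reaction_ids))
  obj <- matrix(NA_real_, length(ids), n_levels, dimnames = list(ids, NULL))
  status <- stats::setNames(character(length(ids)), ids)
  failures <- list()
  for (cid in ids) {
    fd <- map_condition(model, compendium, cid, params, objectives, fix_tol)
    values[cid, ] <- fd$fluxes
    obj[cid, ] <- fd$objective_values
    if (!is.null(names(fd$objective_values)))
      colnames(obj) <- names(fd$objective_values)
    status[cid] <- fd$status
    if (fd$status != "optimal") failures[[cid]] <- attr(fd, "reason")
  }
  structure(list(values = values, objective_values = obj, status = status),
            class = "condition_flux_matrix", failures = failures)
}

#' @export
print.condition_flux_matrix <- function(x, ...) {
  cat(sprintf("<condition_flux_matrix> %d conditions x %d reactions (%d failed)\n",
              nrow(x$values), ncol(x$values), sum(x$status != "optimal")))
  invisible(x)
}

#' Drop features with too few finite values
#'
#' Removes feature columns (genes or fluxes) for which strictly less than
#' `min_finite_fraction` of the values are known and finite; a column with
#' exactly the threshold fraction is kept.
#'
#' @param matrix conditions-by-features numeric matrix, possibly with
#'   `NA`/non-finite entries.
#' @param min_finite_fraction threshold (default 0.10).
#' @return the reduced matrix; dropped column ids are in the `dropped`
#'   attribute.
#' @export
filter_features <- function(matrix, min_finite_fraction = 0.10) {
  frac <- colMeans(is.finite(matrix))
  keep <- frac >= min_finite_fraction
  if (!any(keep))
    stop("all feature columns fall below the finite-fraction threshold", call. = FALSE)
  out <- matrix[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(matrix)[!keep]
  out
}

#' Replace values by within-feature quantile indices
#'
#' Per column, values are replaced by their quantile number in
#' `1..n_quantiles` (average ranks for ties, mapped with
#' `ceiling(rank / n * n_quantiles)` and clamped). The output depends only
#' on within-column ranks, which tames the heavy-tailed (high-kurtosis)
#' distributions of flux and expression values without removing outliers.
#' Missing entries are imputed with the column median first.
#'
#' @param matrix conditions-by-features numeric matrix (after
#'   [filter_features()]).
#' @param n_quantiles number of quantile bins (default 20).
#' @return integer matrix of the same shape.
#' @export
quantile_discretize <- function(matrix, n_quantiles = 20) {
  out <- apply(matrix, 2, function(x) {
    x[!is.finite(x)] <- stats::median(x[is.finite(x)])
    r <- rank(x, ties.method = "average")
    pmin(pmax(ceiling(r / length(x) * n_quantiles), 1L), n_quantiles)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Build a condition-similarity layer from an omic matrix
#'
#' Full per-layer preprocessing: finite-fraction filtering, 20-quantile
#' discretization, pairwise Euclidean distances, then a similarity kernel.
#' The default kernel is the scale-adaptive one ([similarity_scaled_kernel()]),
#' whose local bandwidth keeps similarities usable at any feature
#' dimensionality; `kernel = "exp"` selects the plain
#' \eqn{e^{-d^2}} kernel ([similarity_exp()]), optionally with distances
#' rescaled by their median so the exponent does not underflow on
#' high-dimensional quantile data.
#'
#' @param values conditions-by-features numeric matrix.
#' @param n_quantiles quantile bins (default 20).
#' @param min_finite_fraction finite-fraction filter threshold (default 0.10).
#' @param kernel `"scaled"` (default) or `"exp"`.
#' @param mu,K scaled-kernel parameters (see [similarity_scaled_kernel()]).
#' @param rescale divide distances by their median positive value before
#'   the kernel (default `TRUE`). Quantile-discretized data over many
#'   features has raw Euclidean distances in the tens, which pushes either
#'   exponential kernel into underflow next to the unit diagonal; the
#'   median rescaling puts typical distances at 1 and only changes the
#'   kernel bandwidth (for the scaled kernel, rescaling by `c` maps
#'   \eqn{W \to W^c}).
#' @return a symmetric similarity matrix over conditions.
#' @export
condition_layer <- function(values, n_quantiles = 20, min_finite_fraction = 0.10,
                            kernel = c("scaled", "exp"), mu = 0.5,
                            K = max(2L, ceiling(nrow(values) / 10)),
                            rescale = TRUE) {
  kernel <- match.arg(kernel)
  q <- quantile_discretize(filter_features(values, min_finite_fraction), n_quantiles)
  d <- distance_matrix(q)
  if (rescale) {
    med <- stats::median(d[upper.tri(d)][d[upper.tri(d)] > 0])
    if (is.finite(med) && med > 0) d <- d / med
  }
  if (kernel == "scaled") similarity_scaled_kernel(d, mu = mu, K = K)
  else similarity_exp(d)
}
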