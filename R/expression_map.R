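#' Build an expression compendium
#'
#' Conditions-by-genes matrix of expression values on a ratio-to-reference
#' scale, where 1 is the wild-type (reference) level. Missing entries are
#' allowed and must be `NA`.
#'
#' @param values numeric matrix, conditions as rows, genes as columns.
#' @param condition_ids,gene_ids identifiers; default to dimnames.
#' @param metadata optional data.frame of per-condition flags (e.g. an
#'   `aerobic` logical), one row per condition.
#' @return an object of class `expression_compendium` with fields `values`
#'   and `metadata`.
#' @export
expression_compendium <- function(values, condition_ids = rownames(values),
                                  gene_ids = colnames(values), metadata = NULL) {
  values <- as.matrix(values)
  if (is.null(condition_ids) && nrow(values) == 0) condition_ids <- character(0)
  if (is.null(gene_ids) && ncol(values) == 0) gene_ids <- character(0)
  if (is.null(condition_ids) || is.null(gene_ids))
    stop("condition and gene ids are required", call. = FALSE)
  if (anyDuplicated(condition_ids) || anyDuplicated(gene_ids))
    stop("condition and gene ids must be unique", call. = FALSE)
  finite_vals <- values[is.finite(values)]
  if (any(finite_vals < 0))
    stop("expression values must be >= 0 on the ratio-to-reference scale", call. = FALSE)
  dimnames(values) <- list(condition_ids, gene_ids)
  if (!is.null(metadata) && nrow(metadata) != nrow(values))
    stop("metadata must have one row per condition", call. = FALSE)
  structure(list(values = values, metadata = metadata),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("<expression_compendium> %d conditions x %d genes (%.1f%% finite)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.finite(x$values))))
  invisible(x)
}

#' Read an expression table from delimited text
#'
#' Expects genes as rows and conditions as columns with a header row (the
#' common compendium layout); the result is transposed to the internal
#' conditions-by-genes orientation. Empty fields and `NA` are missing.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param log2_ratio set `TRUE` if values are log2 ratios; they are then
#'   transformed with [ratio_from_log2()] onto the ratio scale.
#' @return an `expression_compendium`.
#' @export
read_expression <- function(path, sep = "\t", log2_ratio = FALSE) {
  tab <- utils::read.delim(path, sep = sep, row.names = 1, check.names = FALSE,
                           na.strings = c("", "NA"))
  values <- t(as.matrix(tab))
  if (log2_ratio) values <- ratio_from_log2(values)
  expression_compendium(values)
}

#' Convert log2-ratio expression to the ratio-to-reference scale
#'
#' Compendia are often distributed as log2 ratios against a reference; the
#' bound map expects plain ratios where 1 is wild type, so the transform is
#' `2^x`.
#'
#' @param x numeric vector or matrix of log2 ratios.
#' @return `2^x`.
#' @export
ratio_from_log2 <- function(x) 2^x

#' Parameters of the logarithmic bound map
#'
#' @param gamma weight of the inverse gene-set variance (dimensionless,
#'   > 0). Larger values let expression changes act more strongly on the
#'   flux bounds of low-variance (putatively important) gene sets.
#' @param log_base base of the logarithm (> 1, default `e`).
#' @param sigma2_floor lower floor applied to gene-set variances so that
#'   constant genes do not divide by zero.
#' @return a list of class `map_parameters`.
#' @export
map_parameters <- function(gamma = 1, log_base = exp(1), sigma2_floor = 1e-6) {
  if (gamma <= 0 || log_base <= 1 || sigma2_floor <= 0)
    stop("require gamma > 0, log_base > 1, sigma2_floor > 0", call. = FALSE)
  structure(list(gamma = gamma, log_base = log_base, sigma2_floor = sigma2_floor),
            class = "map_parameters")
}

#' Gene-set expression of a GPR rule
#'
#' Collapses per-gene expression onto the reaction's gene set: a leaf takes
#' the gene's value, an `AND` node (enzyme complex) the minimum of its
#' children, an `OR` node (isozymes) the maximum. Genes missing from
#' `theta` take the neutral wild-type value 1 (recorded in the
#' `missing_genes` attribute of [gene_set_profile()] output).
#'
#' @param gpr a `gpr` tree (or GPR string).
#' @param theta named numeric vector of per-gene expression values.
#' @param missing_value value substituted for unresolvable genes (default 1).
#' @return a single gene-set expression value.
#' @examples
#' gene_set_expression(parse_gpr("aspC OR tyrB"), c(aspC = 0.4, tyrB = 1.2))
#' @export
gene_set_expression <- function(gpr, theta, missing_value = 1) {
  if (!inherits(gpr, "gpr")) gpr <- parse_gpr(gpr)
  gpr_fold(unclass(gpr), function(g) {
    v <- unname(theta[g])
    if (length(v) != 1 || is.na(v)) missing_value else v
  })
}

#' Gene-set variance of a GPR rule
#'
#' Applies the same min/max recursion as [gene_set_expression()] to per-gene
#' variances computed across conditions, then floors the result at
#' `sigma2_floor`.
#'
#' @param gpr a `gpr` tree (or GPR string).
#' @param var named numeric vector of per-gene variances.
#' @param sigma2_floor lower floor for the result.
#' @param missing_value variance substituted for unresolvable genes; defaults
#'   to `NA`, meaning such leaves are treated as absent information and the
#'   floor applies if everything is missing.
#' @return a single floored gene-set variance.
#' @export
gene_set_variance <- function(gpr, var, sigma2_floor = 1e-6, missing_value = NA_real_) {
  if (!inherits(gpr, "gpr")) gpr <- parse_gpr(gpr)
  v <- gpr_fold(unclass(gpr), function(g) {
    x <- unname(var[g])
    if (length(x) != 1 || is.na(x)) missing_value else x
  })
  if (is.na(v)) return(sigma2_floor)
  max(v, sigma2_floor)
}

#' Logarithmic variance-weighted bound map
#'
#' Maps a gene-set expression value \eqn{\Theta} (ratio to wild type) to a
#' multiplicative factor on the reaction's flux bounds:
#' \deqn{\varphi(\Theta) = \left[1 + \frac{\gamma}{\sigma^2}
#'   \left|\log(\Theta)\right|\right]^{\mathrm{sgn}(\Theta - 1)}}
#' with \eqn{\varphi(1) = 1} and the continuity limit
#' \eqn{\varphi(\Theta) \to 0} as \eqn{\Theta \to 0}. Over-expression
#' (\eqn{\Theta > 1}) relaxes bounds, under-expression tightens them, and
#' the effect is stronger for gene sets with low variance across conditions
#' (which the method treats as important). The map satisfies the reciprocal
#' identity \eqn{\varphi(\Theta)\,\varphi(1/\Theta) = 1}.
#'
#' @param theta_set gene-set expression value(s), \eqn{\ge 0}; vectorized.
#' @param sigma2 gene-set variance(s), recycled against `theta_set`.
#' @param params a [map_parameters()] object.
#' @return multiplicative bound factor(s), same length as `theta_set`.
#' @examples
#' p <- map_parameters(gamma = 1)
#' phi(1, 1, p)        # 1: wild type leaves bounds untouched
#' phi(exp(1), 1, p)   # 2
#' phi(exp(-1), 1, p)  # 0.5
#' @export
phi <- function(theta_set, sigma2, params = map_parameters()) {
  if (any(is.na(theta_set)))
    stop("theta_set contains NA", call. = FALSE)
  if (any(theta_set < 0))
    stop("gene-set expression must be >= 0, got ", min(theta_set), call. = FALSE)
  sigma2 <- pmax(rep_len(ifelse(is.na(sigma2), params$sigma2_floor, sigma2),
                         length(theta_set)),
                 params$sigma2_floor)
  out <- numeric(length(theta_set))
  one <- theta_set == 1
  zero <- theta_set == 0
  out[one] <- 1
  out[zero] <- 0
  rest <- !one & !zero
  if (any(rest)) {
    w <- 1 + (params$gamma / sigma2[rest]) *
      abs(log(theta_set[rest], base = params$log_base))
    out[rest] <- w^sign(theta_set[rest] - 1)
  }
  out
}

#' Per-condition gene-set profile for a model
#'
#' Computes, for every reaction of the model, the gene-set expression
#' \eqn{\Theta_i} in one condition and the gene-set variance
#' \eqn{\sigma_i^2} across all conditions of the compendium (variance is a
#' property of the compendium, not of the single condition). Reactions
#' without a GPR carry the neutral value 1 and a sentinel `NA` variance.
#'
#' @param model a `metabolic_model`.
#' @param compendium an `expression_compendium`.
#' @param condition_id one of the compendium's condition ids.
#' @param params a [map_parameters()] object (supplies the variance floor).
#' @return a list of class `gene_set_profile` with numeric vectors
#'   `theta_set` and `sigma2` (named by reaction) and a `missing_genes`
#'   attribute listing genes absent from the compendium.
#' @export
gene_set_profile <- function(model, compendium, condition_id,
                             params = map_parameters()) {
  if (!condition_id %in% rownames(compendium$values))
    stop("unknown condition id: ", condition_id, call. = FALSE)
  theta <- compendium$values[condition_id, ]
  gvar <- apply(compendium$values, 2, stats::var, na.rm = TRUE)
  n <- length(model$reaction_ids)
  theta_set <- stats::setNames(rep(1, n), model$reaction_ids)
  sigma2 <- stats::setNames(rep(NA_real_, n), model$reaction_ids)
  missing <- setdiff(unique(unlist(lapply(model$gpr, gpr_genes))),
                     colnames(compendium$values))
  for (rid in names(model$gpr)) {
    g <- model$gpr[[rid]]
    theta_set[rid] <- gene_set_expression(g, theta)
    sigma2[rid] <- gene_set_variance(g, gvar, sigma2_floor = params$sigma2_floor)
  }
  structure(list(theta_set = theta_set, sigma2 = sigma2),
            class = "gene_set_profile", missing_genes = missing)
}

#' Apply condition-specific bounds to a model
#'
#' Scales each reaction's default bounds by its \eqn{\varphi(\Theta_i)}
#' factor: effective bounds \eqn{(V^{min}_i \varphi_i,\; V^{max}_i
#' \varphi_i)}. Reactions without a GPR keep their default bounds
#' (\eqn{\varphi = 1}).
#'
#' @param model a `metabolic_model`.
#' @param profile a [gene_set_profile()] for one condition.
#' @param params a [map_parameters()] object.
#' @return the model with scaled `lower_bounds`/`upper_bounds`; the applied
#'   factors are stored in the `phi` attribute.
#' @export
condition_bounds <- function(model, profile, params = map_parameters()) {
  if (length(profile$theta_set) != length(model$reaction_ids))
    stop("profile length does not match model reaction count", call. = FALSE)
  factors <- phi(profile$theta_set, profile$sigma2, params)
  no_gpr <- !model$reaction_ids %in% names(model$gpr)
  factors[no_gpr] <- 1
  model$lower_bounds <- model$lower_bounds * factors
  model$upper_bounds <- model$upper_bounds * factors
  # a negative lower bound scaled by phi stays <= scaled upper bound since phi >= 0
  attr(model, "phi") <- stats::setNames(factors, model$reaction_ids)
  model
}
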