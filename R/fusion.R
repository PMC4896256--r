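#' Pairwise Euclidean distance matrix between conditions
#'
#' @param matrix conditions-by-features numeric matrix without missing
#'   entries (impute first; see [quantile_discretize()]).
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(matrix) {
  if (any(!is.finite(matrix)))
    stop("distance_matrix requires finite entries; impute missing values first",
         call. = FALSE)
  as.matrix(stats::dist(matrix))
}

#' Negative-squared-exponential similarity
#'
#' Entrywise \eqn{P_{ij} = e^{-d_{ij}^2}}; the diagonal is 1.
#'
#' @param d non-negative distance matrix.
#' @return similarity matrix in `[0, 1]`.
#' @export
similarity_exp <- function(d) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  exp(-d^2)
}

#' Scaled exponential similarity kernel
#'
#' \eqn{W_{ij} = \exp(-\rho_{ij}^2 / (\mu\,\epsilon_{ij}))} with local
#' bandwidth \eqn{\epsilon_{ij} = (\bar\rho_{i,K} + \bar\rho_{j,K} +
#' \rho_{ij})/3}, where \eqn{\bar\rho_{i,K}} is the mean distance from node
#' `i` to its `K` nearest neighbours (self excluded). The local bandwidth
#' adapts to the data's distance scale: rescaling all distances by
#' `c > 0` rescales \eqn{\epsilon} linearly too, so the similarities
#' transform as the power \eqn{W^c} instead of collapsing the way the
#' fixed-bandwidth \eqn{e^{-d^2}} kernel does. When \eqn{\epsilon_{ij} = 0}
#' the similarity is 1 by continuity.
#'
#' @param d non-negative distance matrix.
#' @param mu kernel scale (> 0, typically 0.3--0.8).
#' @param K neighbourhood size for the local bandwidth.
#' @return symmetric similarity matrix in `(0, 1]` with unit diagonal.
#' @export
similarity_scaled_kernel <- function(d, mu = 0.5, K = 20) {
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  n <- nrow(d)
  if (K < 1 || K > n - 1) stop("K must be in [1, n-1]", call. = FALSE)
  mean_k <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i])[seq_len(K)])
  }, numeric(1))
  eps <- (outer(mean_k, mean_k, "+") + d) / 3
  W <- ifelse(eps == 0, 1, exp(-d^2 / (mu * eps)))
  (W + t(W)) / 2
}

#' Normalize a native similarity matrix into [0, 1]
#'
#' For layers whose edge weights are already similarities (e.g. event
#' counts), squares the entries and divides by the maximum.
#'
#' @param similarities non-negative matrix.
#' @return matrix with maximum entry 1.
#' @export
normalize_native <- function(similarities) {
  if (any(!is.finite(similarities)))
    stop("similarities must be finite", call. = FALSE)
  sq <- similarities^2
  mx <- max(sq)
  if (mx == 0) stop("cannot normalize an all-zero similarity matrix", call. = FALSE)
  sq / mx
}

#' Initial status matrix P0 from a similarity layer
#'
#' Two normalizations of \eqn{W} into a row-stochastic status matrix:
#' `"row_stochastic"` is \eqn{P_0 = D^{-1} W} with \eqn{D_{ii} = \sum_j
#' W_{ij}}; `"robust"` (the default, more robust to numerical
#' instabilities) sets \eqn{P_0(i,j) = W_{ij} / (2 \sum_{k \ne i} W_{ik})}
#' off the diagonal and \eqn{1/2} on it, so each row splits its mass evenly
#' between self and neighbours.
#'
#' @param W similarity matrix with positive row sums.
#' @param method `"robust"` or `"row_stochastic"`.
#' @return row-stochastic matrix (rows sum to 1).
#' @export
normalize_p0 <- function(W, method = c("robust", "row_stochastic")) {
  method <- match.arg(method)
  n <- nrow(W)
  if (method == "row_stochastic") {
    rs <- rowSums(W)
    zero <- which(rs == 0)
    if (length(zero))
      stop("zero row sum for node(s): ",
           paste(rownames(W)[zero] %||% zero, collapse = ", "), call. = FALSE)
    return(W / rs)
  }
  off <- rowSums(W) - diag(W)
  zero <- which(off == 0)
  if (length(zero))
    stop("zero off-diagonal row sum for node(s): ",
         paste(rownames(W)[zero] %||% zero, collapse = ", "), call. = FALSE)
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local affinity matrix (K-nearest-neighbour kernel)
#'
#' Keeps each row's similarity to its `K` most similar nodes (self always
#' included, counted within `K`; ties broken by column order), zeros
#' elsewhere, then row-normalizes to sum 1. This is the sparse "message
#' passing" kernel of the fusion iteration.
#'
#' @param W similarity matrix.
#' @param K neighbourhood size, `1 <= K < n`.
#' @return row-stochastic matrix whose row `i` is supported on the
#'   neighbourhood of `i`.
#' @export
local_affinity <- function(W, K) {
  n <- nrow(W)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < n", call. = FALSE)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    others <- setdiff(order(W[i, ], decreasing = TRUE), i)
    nbrs <- c(i, others[seq_len(K - 1L)])
    S[i, nbrs] <- W[i, nbrs]
    rs <- sum(S[i, ])
    if (rs > 0) S[i, ] <- S[i, ] / rs else S[i, i] <- 1
  }
  S
}

#' One bias-weighted fusion update across layers
#'
#' Updates every layer's status matrix from the bias-weighted mean of the
#' other layers, diffused through its own local kernel:
#' \deqn{P^{(v)} \leftarrow S^{(v)} \left(\frac{\sum_{k \ne v} b_k
#'   P^{(k)}}{\sum_{k \ne v} b_k}\right) (S^{(v)})^\top}
#' followed by symmetrization \eqn{(P + P^\top)/2} and the robust
#' row renormalization of [normalize_p0()]. With equal biases this is
#' exactly the unweighted update (the plain mean over the other layers);
#' for `m = 2` the bias cancels entirely, so a two-layer bias acts only
#' through the final aggregation in [fuse()]. Each layer's update reads
#' only pre-update state, so layers could be updated concurrently with
#' identical results.
#'
#' @param P_list list of current status matrices (row-stochastic).
#' @param S_list list of local kernels from [local_affinity()].
#' @param b positive bias vector, one entry per layer.
#' @param renormalize apply symmetrization + renormalization (default
#'   `TRUE`; disable to inspect the raw update).
#' @return list of updated status matrices.
#' @export
weighted_update <- function(P_list, S_list, b = rep(1, length(P_list)),
                            renormalize = TRUE) {
  m <- length(P_list)
  if (length(S_list) != m || length(b) != m)
    stop("P_list, S_list and b must have one entry per layer", call. = FALSE)
  if (any(b <= 0)) stop("biases must be > 0", call. = FALSE)
  dims <- vapply(c(P_list, S_list), function(x) paste(dim(x), collapse = "x"), character(1))
  if (length(unique(dims)) != 1)
    stop("all layer matrices must be square and conformable", call. = FALSE)
  lapply(seq_len(m), function(v) {
    others <- setdiff(seq_len(m), v)
    mix <- Reduce(`+`, lapply(others, function(k) b[k] * P_list[[k]])) / sum(b[others])
    P <- S_list[[v]] %*% mix %*% t(S_list[[v]])
    if (renormalize) {
      P <- (P + t(P)) / 2
      P <- normalize_p0(P, "robust")
    }
    P
  })
}

#' Assemble a multiplex network of similarity layers
#'
#' @param layers list of >= 2 symmetric similarity matrices over the same
#'   ordered node set (conditions).
#' @param bias positive per-layer confidence weights; e.g. `c(2, 1)` trusts
#'   the first (phenotype) layer twice as much as the second
#'   (transcriptome).
#' @param K neighbourhood size for the local kernels.
#' @param max_iter maximum fusion iterations.
#' @param tol1,tol2 convergence tolerances on the change scalar and on its
#'   discrete derivative (see [fuse()]).
#' @return an object of class `multiplex_network`.
#' @export
multiplex_network <- function(layers, bias = rep(1, length(layers)),
                              K = max(2L, ceiling(nrow(layers[[1]]) / 10)),
                              max_iter = 20, tol1 = 1e-6, tol2 = 1e-6) {
  if (length(layers) < 2) stop("a multiplex needs at least 2 layers", call. = FALSE)
  n <- nrow(layers[[1]])
  ids <- rownames(layers[[1]])
  for (l in layers) {
    if (!is.matrix(l) || nrow(l) != n || ncol(l) != n)
      stop("layers must be square matrices over the same node set", call. = FALSE)
    if (!isTRUE(all.equal(rownames(l), ids)))
      stop("layers must share an identical node ordering", call. = FALSE)
    if (max(abs(l - t(l))) > 1e-12)
      stop("layers must be symmetric", call. = FALSE)
    if (any(l < 0)) stop("layer similarities must be non-negative", call. = FALSE)
  }
  if (length(bias) != length(layers) || any(bias <= 0))
    stop("bias must be a positive vector with one entry per layer", call. = FALSE)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < n", call. = FALSE)
  structure(list(layers = layers, bias = bias, K = K, max_iter = max_iter,
                 tol1 = tol1, tol2 = tol2, node_ids = ids),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d layers x %d nodes; bias = %s; K = %d\n",
              length(x$layers), nrow(x$layers[[1]]),
              paste(x$bias, collapse = ":"), x$K))
  invisible(x)
}

#' Fuse a multiplex network into a single similarity network
#'
#' Iterates [weighted_update()] until the layers agree. Convergence is
#' detected from the first and second discrete derivatives of the change
#' scalar \eqn{c_n} (mean relative Frobenius change across layers): the
#' iteration stops when \eqn{c_n < tol_1} and \eqn{|c_n - c_{n-1}| <
#' tol_2}, or at `max_iter`. If \eqn{c_n} increases for 5 consecutive
#' iterations the run is flagged divergent and the partial result
#' returned. The fused network is the bias-weighted average
#' \eqn{\sum_v b_v P^{(v)} / \sum_v b_v} (symmetrized), so the bias always
#' acts on the aggregate even in the two-layer case where it cancels inside
#' the update; `bias_in_update = FALSE` restricts the bias to this final
#' aggregation only.
#'
#' @param network a [multiplex_network()].
#' @param bias_in_update apply the bias inside each update step as well as
#'   in the final aggregation (default `TRUE`).
#' @return an object of class `fusion_result`: list with `fused` (symmetric
#'   similarity matrix), `iterations`, `trace` (per-iteration \eqn{c_n}),
#'   `converged` and `diverged` flags, and the per-layer final status
#'   matrices in `layers`.
#' @export
fuse <- function(network, bias_in_update = TRUE) {
  stopifnot(inherits(network, "multiplex_network"))
  P <- lapply(network$layers, normalize_p0, method = "robust")
  S <- lapply(network$layers, local_affinity, K = network$K)
  b_upd <- if (bias_in_update) network$bias else rep(1, length(P))
  trace <- numeric(0)
  converged <- FALSE
  diverged <- FALSE
  rising <- 0L
  iter <- 0L
  while (iter < network$max_iter) {
    iter <- iter + 1L
    P_new <- weighted_update(P, S, b_upd)
    cn <- mean(vapply(seq_along(P), function(v) {
      norm(P_new[[v]] - P[[v]], "F") / norm(P[[v]], "F")
    }, numeric(1)))
    P <- P_new
    trace <- c(trace, cn)
    if (length(trace) >= 2 && cn > trace[length(trace) - 1]) {
      rising <- rising + 1L
      if (rising >= 5L) { diverged <- TRUE; break }
    } else rising <- 0L
    if (cn < network$tol1 &&
        (length(trace) == 1 || abs(cn - trace[length(trace) - 1]) < network$tol2)) {
      converged <- TRUE
      break
    }
  }
  w <- network$bias / sum(network$bias)
  fused <- Reduce(`+`, Map(`*`, w, P))
  fused <- (fused + t(fused)) / 2
  if (!is.null(network$node_ids))
    dimnames(fused) <- list(network$node_ids, network$node_ids)
  structure(list(fused = fused, iterations = iter, trace = trace,
                 converged = converged, diverged = diverged, layers = P),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d nodes; %d iteration(s); %s\n",
              nrow(x$fused), x$iterations,
              if (x$diverged) "DIVERGED (partial result)"
              else if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Read/write a similarity layer as delimited text
#'
#' Square matrix with node ids as header row and first column.
#'
#' @param path file path.
#' @return `read_layer`: a named similarity matrix.
#' @export
read_layer <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_layer
#' @param layer similarity matrix to write.
#' @return `write_layer`: `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  utils::write.table(data.frame(node_id = rownames(layer), layer,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
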