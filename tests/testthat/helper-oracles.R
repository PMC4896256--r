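# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no solve_lp, no gpr_fold, no format_gpr).

# All vertices of {v : Sv = 0, lb <= v <= ub} by exhaustive basis enumeration:
# fix n - rank(S) coordinates at a bound, solve for the rest, keep feasible
# unique solutions. Only meant for tiny models (n <= 8).
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  free_sets <- if (r == 0) list(integer(0)) else utils::combn(n, r, simplify = FALSE)
  verts <- list()
  for (fs in free_sets) {
    fixed <- setdiff(seq_len(n), fs)
    if (length(fs) > 0) {
      Sf <- S[, fs, drop = FALSE]
      if (qr(Sf)$rank < length(fs)) next
    }
    for (mask in 0:(2^length(fixed) - 1)) {
      bits <- as.integer(intToBits(mask))[seq_along(fixed)]
      v <- numeric(n)
      v[fixed] <- ifelse(bits == 1, ub[fixed], lb[fixed])
      if (length(fs) > 0) {
        rhs <- -S[, fixed, drop = FALSE] %*% v[fixed]
        sol <- tryCatch(qr.solve(S[, fs, drop = FALSE], rhs),
                        error = function(e) NULL)
        if (is.null(sol)) next
        v[fs] <- sol
      }
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 8)), , drop = FALSE]
}

# Lexicographic optimum by filtering vertices level by level.
lex_vertex_oracle <- function(model, objectives, tol = 1e-6) {
  V <- enumerate_vertices(model$S, model$lower_bounds, model$upper_bounds)
  stopifnot(nrow(V) > 0)
  optima <- numeric(0)
  for (obj in objectives) {
    sel <- numeric(ncol(V))
    names(sel) <- model$reaction_ids
    sel[obj] <- 1
    vals <- as.numeric(V %*% sel)
    z <- max(vals)
    optima <- c(optima, z)
    V <- V[vals >= z - tol, , drop = FALSE]
  }
  optima
}

# Random GPR tree with its own text rendering (always fully parenthesized)
# and its own evaluator; independent of parse_gpr/format_gpr/gpr_fold.
random_gpr_tree <- function(depth, genes, p_leaf = 0.3) {
  if (depth == 0 || runif(1) < p_leaf)
    return(list(kind = "leaf", gene = sample(genes, 1)))
  op <- sample(c("AND", "OR"), 1)
  k <- sample(2:3, 1)
  list(kind = "node", op = op,
       kids = lapply(seq_len(k), function(i) random_gpr_tree(depth - 1, genes, p_leaf)))
}

render_gpr_tree <- function(tree) {
  if (tree$kind == "leaf") return(tree$gene)
  inner <- vapply(tree$kids, render_gpr_tree, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", tree$op, " ")), ")")
}

eval_gpr_tree <- function(tree, theta) {
  if (tree$kind == "leaf") return(theta[[tree$gene]])
  vals <- vapply(tree$kids, eval_gpr_tree, numeric(1), theta = theta)
  if (tree$op == "AND") min(vals) else max(vals)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# within/between-block contrast ratio of a similarity matrix, diagonal excluded
block_contrast <- function(W, labels) {
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(W[which(same)], na.rm = TRUE) / mean(W[which(!same)], na.rm = TRUE)
}
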