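#' Spectral clustering of a similarity network
#'
#' Normalized-Laplacian spectral clustering: the top `k` eigenvectors of
#' \eqn{D^{-1/2} W D^{-1/2}} are row-normalized and clustered with k-means
#' (deterministic given `seed`; 20 restarts). If the similarity graph has
#' more connected components than `k` a warning is issued and labels are
#' still returned.
#'
#' @param fused symmetric non-negative similarity matrix (e.g. the `fused`
#'   field of a [fuse()] result).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for the k-means initialization.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (named integer vector in `1..k`), `k`, and `ordering` (a permutation
#'   of conditions grouping the clusters, for export).
#' @export
spectral_cluster <- function(fused, k, seed = 1L) {
  n <- nrow(fused)
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  W <- (fused + t(fused)) / 2
  ids <- rownames(W) %||% as.character(seq_len(n))
  if (k == 1) {
    labels <- stats::setNames(rep(1L, n), ids)
    return(structure(list(labels = labels, k = 1L, ordering = seq_len(n)),
                     class = "cluster_assignment"))
  }
  n_comp <- n_components(W > max(W) * 1e-12)
  if (n_comp > k)
    warning(sprintf("similarity graph has %d connected components but k = %d", n_comp, k),
            call. = FALSE)
  d <- rowSums(W)
  d[d == 0] <- 1
  Dm <- 1 / sqrt(d)
  L <- W * outer(Dm, Dm)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, stats::kmeans(U, centers = k, nstart = 20, iter.max = 100))
  labels <- stats::setNames(as.integer(km$cluster), ids)
  structure(list(labels = labels, k = as.integer(k),
                 ordering = order(labels)),
            class = "cluster_assignment")
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

n_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d; sizes: %s\n", x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Attribute clusters to dominant features with a shallow decision tree
#'
#' Fits a CART classification tree (Gini impurity) on the feature matrix
#' against the cluster labels, pruned to at most `max_rules` splits, and
#' reports which features the splits use, their thresholds, normalized
#' importances and the training accuracy. A tree with two rules splitting
#' on flux values is typically enough to tell the clusters apart when the
#' clustering is flux-driven.
#'
#' @param features conditions-by-features numeric matrix (e.g. the flux
#'   matrix); rows must align with `labels`.
#' @param labels integer cluster labels (from [spectral_cluster()] or its
#'   `labels` field).
#' @param max_rules maximum number of splits (default 2).
#' @param seed integer seed (tree fitting is deterministic; the seed guards
#'   any tie-breaking).
#' @return an object of class `attribution_report`: list with `importance`
#'   (named fractions summing to 1 over used features), `splits`
#'   (data.frame of `feature`, `threshold`), `split_features`, `accuracy`
#'   (training), and `n_rules`.
#' @export
attribute_clusters <- function(features, labels, max_rules = 2, seed = 1L) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("attribution needs at least 2 clusters", call. = FALSE)
  if (!is.numeric(features))
    stop("features must be a numeric matrix", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("features and labels must cover the same conditions", call. = FALSE)
  df <- as.data.frame(features)
  names(df) <- make.names(colnames(features), unique = TRUE)
  feature_key <- stats::setNames(colnames(features), names(df))
  df$.cluster <- factor(labels)
  fit <- with_seed(seed, rpart::rpart(
    .cluster ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                   xval = 0, maxsurrogate = 0)))
  # prune to the largest subtree with <= max_rules splits
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_rules
  cp_use <- cpt[max(which(ok)), "CP"]
  fit <- rpart::prune(fit, cp = cp_use)
  used <- fit$frame$var[fit$frame$var != "<leaf>"]
  splits <- if (length(used)) {
    sp <- fit$splits
    primary <- sp[rownames(sp) %in% used & sp[, "adj"] == 0, , drop = FALSE]
    data.frame(feature = unname(feature_key[rownames(primary)]),
               threshold = unname(primary[, "index"]),
               stringsAsFactors = FALSE)
  } else data.frame(feature = character(0), threshold = numeric(0))
  vi <- fit$variable.importance
  importance <- if (is.null(vi)) stats::setNames(numeric(0), character(0)) else {
    stats::setNames(as.numeric(vi) / sum(vi), unname(feature_key[names(vi)]))
  }
  pred <- stats::predict(fit, df, type = "class")
  accuracy <- mean(as.integer(as.character(pred)) == labels)
  structure(list(importance = importance,
                 splits = splits,
                 split_features = unique(unname(feature_key[as.character(used)])),
                 accuracy = accuracy,
                 n_rules = length(used),
                 tree = fit),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report> %d rule(s); training accuracy %.3f\n",
              x$n_rules, x$accuracy))
  if (length(x$importance)) {
    top <- sort(x$importance, decreasing = TRUE)
    cat("  importance:",
        paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bootstrap stability of attribution features
#'
#' Repeats [attribute_clusters()] on resamples of `frac` of the conditions
#' drawn without replacement and reports, per feature, the fraction of
#' resamples in which it appears among the tree's split features. Features
#' that drive the clustering should be rediscovered in (nearly) every
#' resample; noise features should not.
#'
#' @inheritParams attribute_clusters
#' @param n_resamples number of resamples (default 100); 0 returns an empty
#'   report.
#' @param frac fraction of conditions per resample (default 0.80).
#' @return named numeric vector: per-feature stability in `[0, 1]` (all
#'   features of the matrix, 0 when never selected). The top-ranked feature
#'   of each resample is recorded in the `top_feature` attribute.
#' @export
bootstrap_stability <- function(features, labels, n_resamples = 100,
                                frac = 0.80, max_rules = 2, seed = 1L) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  if (n_resamples == 0)
    return(stats::setNames(numeric(0), character(0)))
  n <- nrow(features)
  m <- max(2L, floor(frac * n))
  hits <- stats::setNames(numeric(ncol(features)), colnames(features))
  top <- character(n_resamples)
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      tries <- 0L
      repeat {
        idx <- sample.int(n, m)
        if (length(unique(labels[idx])) >= 2) break
        tries <- tries + 1L
        if (tries > 100L)
          stop("could not draw a resample containing >= 2 clusters", call. = FALSE)
      }
      rep_r <- attribute_clusters(features[idx, , drop = FALSE], labels[idx],
                                  max_rules = max_rules, seed = seed + r)
      hits[rep_r$split_features] <- hits[rep_r$split_features] + 1
      top[r] <- if (length(rep_r$importance))
        names(rep_r$importance)[which.max(rep_r$importance)] else NA_character_
    }
  })
  out <- hits / n_resamples
  attr(out, "top_feature") <- top
  out
}

#' Reorder a similarity matrix by cluster for export
#'
#' Permutes rows and columns so clusters form contiguous blocks (heat-map
#' ordering), optionally carrying per-condition annotation columns (e.g. a
#' selected flux) alongside.
#'
#' @param fused symmetric similarity matrix.
#' @param labels cluster labels (vector or `cluster_assignment`).
#' @param annotations optional per-condition data.frame or matrix, rows
#'   aligned with `fused`.
#' @return list with `matrix` (reordered), `order` (the permutation),
#'   `labels` (reordered), and `annotations` (reordered or `NULL`).
#' @export
export_ordered_matrix <- function(fused, labels, annotations = NULL) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  ord <- order(labels)
  list(matrix = fused[ord, ord, drop = FALSE],
       order = ord,
       labels = labels[ord],
       annotations = if (is.null(annotations)) NULL else
         annotations[ord, , drop = FALSE])
}
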