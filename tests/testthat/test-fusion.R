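# small symmetric similarity matrix with positive entries
rand_sim <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.05, 1), n, n)
  W <- (A + t(A)) / 2
  diag(W) <- 1
  W
}

test_that("distance_matrix computes Euclidean distances", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- distance_matrix(x)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  # triangle inequality on random matrices
  set.seed(2)
  for (i in 1:5) {
    d <- distance_matrix(matrix(rnorm(8 * 3), 8, 3))
    for (a in 1:8) for (b in 1:8) for (cc in 1:8)
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
  }
  expect_error(distance_matrix(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("similarity_exp is exp(-d^2) with unit diagonal", {
  d <- rbind(c(0, 1), c(1, 0))
  P <- similarity_exp(d)
  expect_equal(P[1, 1], 1)
  expect_equal(P[1, 2], exp(-1))
  # strictly decreasing in distance
  ds <- seq(0, 3, by = 0.1)
  expect_true(all(diff(similarity_exp(matrix(ds, 1))) < 0))
  expect_error(similarity_exp(matrix(-1, 1, 1)), "non-negative")
})

test_that("scaled kernel matches its closed form and is scale invariant", {
  # symmetric 3-node configuration engineered so mu * eps = 1 for pair (1,2):
  # distances d12 = 1, d13 = d23 = 1; K = 1 neighbour means eps = (1+1+1)/3 = 1
  d <- matrix(1, 3, 3); diag(d) <- 0
  W <- similarity_scaled_kernel(d, mu = 1, K = 1)
  expect_equal(W[1, 2], exp(-1))
  expect_equal(unname(diag(similarity_scaled_kernel(d, mu = 0.5, K = 1))),
               rep(1, 3))  # rho = 0 on the diagonal

  # rescaling all distances by c raises the similarities to the power c,
  # because the local bandwidth eps scales linearly with the distances
  set.seed(3)
  x <- matrix(rnorm(10 * 4), 10, 4)
  d1 <- distance_matrix(x)
  W1 <- similarity_scaled_kernel(d1, mu = 0.6, K = 3)
  W2 <- similarity_scaled_kernel(7.3 * d1, mu = 0.6, K = 3)
  expect_equal(W2, W1^7.3, tolerance = 1e-10)

  # all-identical points: eps = 0 handled by continuity
  d0 <- matrix(0, 4, 4)
  expect_equal(unname(similarity_scaled_kernel(d0, mu = 1, K = 2)),
               matrix(1, 4, 4))
})

test_that("normalize_native squares and divides by the maximum", {
  W <- matrix(c(1, 2, 2, 1), 2)
  out <- normalize_native(W)
  expect_equal(out, matrix(c(0.25, 1, 1, 0.25), 2))
  expect_equal(max(out), 1)
  # order preserving
  a <- matrix(runif(16), 4)
  expect_identical(order(normalize_native(a)), order(a))
  expect_error(normalize_native(matrix(0, 2, 2)), "all-zero")
})

test_that("P0 normalizations are row-stochastic; robust form has diagonal 1/2", {
  set.seed(4)
  for (i in 1:5) {
    W <- rand_sim(10, i)
    P <- normalize_p0(W, "robust")
    expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-12)
    expect_equal(unname(diag(P)), rep(0.5, 10))
    P2 <- normalize_p0(W, "row_stochastic")
    expect_equal(unname(rowSums(P2)), rep(1, 10), tolerance = 1e-12)
  }
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_p0(W, "robust"), matrix(0.5, 2, 2))
  Wz <- matrix(0, 3, 3); diag(Wz) <- 1
  expect_error(normalize_p0(Wz, "robust"), "zero off-diagonal")
  expect_error(normalize_p0(matrix(0, 2, 2), "row_stochastic"), "zero row")
})

test_that("local affinity keeps exactly the K-neighbourhood and row-normalizes", {
  W <- rand_sim(8, 9)
  S <- local_affinity(W, K = 4)
  expect_equal(unname(rowSums(S)), rep(1, 8))
  expect_true(all(rowSums(S > 0) == 4))
  expect_true(all(diag(S) > 0))  # self always included
  # entries outside the neighbourhood are exactly zero
  expect_true(all(S[S != 0] > 0) && sum(S == 0) == 8 * 4)

  # K = 1 keeps only self
  S1 <- local_affinity(W, K = 1)
  expect_equal(unname(S1), diag(8))
  # K = n - 1 keeps all but the weakest non-self entry per row
  Sfull <- local_affinity(W, K = 7)
  expect_true(all(rowSums(Sfull > 0) == 7))
  expect_error(local_affinity(W, 8), "1 <= K < n")
})

test_that("weighted update reduces to the unweighted mean under equal biases", {
  set.seed(10)
  n <- 12
  P <- lapply(1:3, function(i) normalize_p0(rand_sim(n, i), "robust"))
  S <- lapply(1:3, function(i) local_affinity(rand_sim(n, i), 5))
  eq <- weighted_update(P, S, b = c(2, 2, 2), renormalize = FALSE)
  # unweighted reference update computed directly
  ref <- lapply(1:3, function(v) {
    others <- setdiff(1:3, v)
    S[[v]] %*% (Reduce(`+`, P[others]) / 2) %*% t(S[[v]])
  })
  expect_equal(eq, ref, tolerance = 1e-14)

  # m = 2: the per-iteration update is bias-invariant
  P2 <- P[1:2]; S2 <- S[1:2]
  u_a <- weighted_update(P2, S2, b = c(1, 1))
  u_b <- weighted_update(P2, S2, b = c(20, 1))
  expect_equal(u_a, u_b, tolerance = 1e-14)

  # unequal biases tilt the mixed matrix towards the heavier layer
  u3 <- weighted_update(P, S, b = c(100, 1, 1), renormalize = FALSE)
  tilt <- S[[2]] %*% P[[1]] %*% t(S[[2]])
  expect_lt(norm(u3[[2]] - tilt, "F"),
            norm(eq[[2]] - tilt, "F"))

  expect_error(weighted_update(P, S, b = c(1, 1)), "one entry per layer")
  expect_error(weighted_update(P, S, b = c(1, -1, 1)), "> 0")
})

test_that("each fusion iteration preserves row-stochasticity and near-symmetry", {
  set.seed(12)
  W <- lapply(1:2, function(i) rand_sim(15, 20 + i))
  net <- multiplex_network(W, bias = c(2, 1), K = 6, max_iter = 6)
  P <- lapply(net$layers, normalize_p0, method = "robust")
  S <- lapply(net$layers, local_affinity, K = net$K)
  for (it in 1:6) {
    P <- weighted_update(P, S, net$bias)
    for (M in P) {
      # exact row-stochasticity after the closing renormalization; the
      # renormalization leaves a small asymmetry that the next iteration's
      # symmetrization absorbs
      expect_equal(unname(rowSums(M)), rep(1, 15), tolerance = 1e-8)
      expect_lt(max(abs(M - t(M))), 0.05)
      sym <- (M + t(M)) / 2
      expect_lt(max(abs(sym - t(sym))), 1e-12)
    }
  }
})

test_that("fusion fixed points and the no-iteration contract hold", {
  # exact constant-block similarity: two identical layers stay put
  labels <- rep(1:3, each = 6)
  W <- ifelse(outer(labels, labels, "=="), 0.8, 0)
  net <- multiplex_network(list(W, W), K = 6, max_iter = 10)
  res <- fuse(net)
  expect_true(res$converged)
  expect_equal(res$fused, normalize_p0(W, "robust"), tolerance = 1e-9)

  # max_iter = 0: fused is the bias-weighted average of the P0 matrices
  W2 <- rand_sim(12, 31); W3 <- rand_sim(12, 32)
  net0 <- multiplex_network(list(W2, W3), bias = c(3, 1), K = 5, max_iter = 0)
  res0 <- fuse(net0)
  expect_identical(res0$iterations, 0L)
  p0 <- (3 * normalize_p0(W2, "robust") + normalize_p0(W3, "robust")) / 4
  expect_equal(res0$fused, (p0 + t(p0)) / 2, tolerance = 1e-12)

  # the bias moves the aggregate monotonically between the two layers
  net_b <- function(b1) multiplex_network(list(W2, W3), bias = c(b1, 1),
                                          K = 5, max_iter = 4)
  f1 <- fuse(net_b(1))$fused
  f2 <- fuse(net_b(2))$fused
  f4 <- fuse(net_b(4))$fused
  moved <- (f2 - f1) * (f4 - f2)
  expect_true(all(moved[abs(f4 - f1) > 1e-10] > 0))
})

test_that("fusion is permutation-equivariant", {
  spec <- fixture_spec(seed = 5, n_conditions = 24, n_clusters = 3)
  net <- planted_multiplex(spec, K = 8)
  res <- fuse(net)
  perm <- sample(24)
  layers_p <- lapply(net$layers, function(W) W[perm, perm])
  net_p <- multiplex_network(layers_p, bias = net$bias, K = net$K,
                             max_iter = net$max_iter)
  res_p <- fuse(net_p)
  expect_equal(res_p$fused, res$fused[perm, perm], tolerance = 1e-10)
})

test_that("multiplex validation rejects malformed inputs", {
  W <- rand_sim(6, 1)
  expect_error(multiplex_network(list(W)), "at least 2")
  expect_error(multiplex_network(list(W, W[1:5, 1:5])), "square")
  asym <- W; asym[1, 2] <- asym[1, 2] + 1e-3
  expect_error(multiplex_network(list(W, asym)), "symmetric")
  expect_error(multiplex_network(list(W, W), bias = c(1, 0)), "positive")
  expect_error(multiplex_network(list(W, W), K = 6), "K must")
})

test_that("similarity layers round-trip through delimited text", {
  W <- rand_sim(5, 77)
  dimnames(W) <- list(paste0("n", 1:5), paste0("n", 1:5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layer(W, path)
  expect_equal(read_layer(path), W, tolerance = 1e-12)
})
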