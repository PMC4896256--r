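test_that("gene-set expression follows the min/max recursion", {
  expect_equal(gene_set_expression(parse_gpr("aspC OR tyrB"),
                                   c(aspC = 0.4, tyrB = 1.2)), 1.2)
  expect_equal(gene_set_expression(parse_gpr("g"), c(g = 0.5)), 0.5)
  expect_equal(gene_set_expression(parse_gpr("(g1 AND g2) OR g3"),
                                   c(g1 = 2.0, g2 = 0.5, g3 = 1.0)),
               max(min(2.0, 0.5), 1.0))
  # missing genes take the neutral wild-type value
  expect_equal(gene_set_expression(parse_gpr("g1 AND gMissing"), c(g1 = 3)), 1)
})

test_that("gene-set expression matches a brute-force tree oracle", {
  set.seed(7)
  genes <- paste0("g", 1:8)
  for (i in 1:50) {
    tree <- random_gpr_tree(depth = 4, genes = genes)
    theta <- stats::setNames(stats::runif(length(genes), 0, 3), genes)
    got <- gene_set_expression(parse_gpr(render_gpr_tree(tree)), theta)
    expect_equal(got, eval_gpr_tree(tree, theta))
    # bounded by the leaf values
    expect_gte(got, min(theta))
    expect_lte(got, max(theta))
  }
})

test_that("gene-set variance uses the same recursion with flooring", {
  expect_equal(gene_set_variance(parse_gpr("g1 AND g2"),
                                 c(g1 = 0.1, g2 = 0.4)), 0.1)
  expect_equal(gene_set_variance(parse_gpr("g"), c(g = 0)), 1e-6)
  expect_equal(gene_set_variance(parse_gpr("g1 OR g2"),
                                 c(g1 = 0.3, g2 = 0.3)), 0.3)
  expect_equal(gene_set_variance(parse_gpr("g1 OR g2"), c(g1 = NA, g2 = NA)), 1e-6)
})

test_that("phi matches its closed form and limits", {
  p <- map_parameters(gamma = 1)
  expect_identical(phi(1, 5, p), 1)
  expect_equal(phi(exp(1), 1, p), 2)
  expect_equal(phi(exp(-1), 1, p), 0.5)
  expect_identical(phi(0, 1, p), 0)
  expect_error(phi(-0.1, 1, p), ">= 0")
  # log base is configurable: base 2 makes theta = 2 map to 1 + gamma/sigma2
  p2 <- map_parameters(gamma = 3, log_base = 2)
  expect_equal(phi(2, 1, p2), 4)
})

test_that("phi satisfies reciprocal symmetry and monotonicity", {
  p <- map_parameters(gamma = 0.7, sigma2_floor = 1e-9)
  grid <- 10^seq(-3, 3, length.out = 41)
  expect_true(all(abs(phi(grid, 0.5, p) * phi(1 / grid, 0.5, p) - 1) < 1e-12))
  vals <- phi(grid, 0.5, p)
  expect_true(all(diff(vals) > 0))
  # larger gamma pushes phi further from 1 on both sides
  lo <- map_parameters(gamma = 0.5); hi <- map_parameters(gamma = 2)
  expect_lt(phi(0.4, 1, hi), phi(0.4, 1, lo))
  expect_gt(phi(2.5, 1, hi), phi(2.5, 1, lo))
})

test_that("condition_bounds scales bounds via phi and spares GPR-free reactions", {
  m <- toy_model("chain")
  comp <- expression_compendium(
    matrix(1, 2, 5, dimnames = list(c("c1", "c2"), m$gene_ids)))
  prof <- gene_set_profile(m, comp, "c1")
  b <- condition_bounds(m, prof)
  expect_equal(b$lower_bounds, m$lower_bounds)
  expect_equal(b$upper_bounds, m$upper_bounds)

  # theta = e with sigma2 = 1 doubles the bound
  prof$theta_set["uptake"] <- exp(1)
  prof$sigma2["uptake"] <- 1
  b2 <- condition_bounds(m, prof)
  expect_equal(unname(b2$upper_bounds["uptake"]), 20)

  # theta = 0 closes the reaction
  prof$theta_set["uptake"] <- 0
  b3 <- condition_bounds(m, prof)
  expect_equal(unname(b3$upper_bounds["uptake"]), 0)
  expect_equal(unname(b3$lower_bounds["uptake"]), 0)

  prof$theta_set <- prof$theta_set[-1]
  expect_error(condition_bounds(m, prof), "length")
})

test_that("expression tables read from delimited text with genes as rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g2\t0.5\t"), path)
  comp <- read_expression(path)
  expect_identical(rownames(comp$values), c("c1", "c2"))
  expect_identical(colnames(comp$values), c("g1", "g2"))
  expect_true(is.na(comp$values["c2", "g2"]))
  # log2-ratio input lands on the ratio scale
  comp2 <- read_expression(path, log2_ratio = TRUE)
  expect_equal(unname(comp2$values["c2", "g1"]), 4)
  expect_equal(ratio_from_log2(c(-1, 0, 1)), c(0.5, 1, 2))
})
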