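test_that("single-level FBA solves the toy chain and degenerate cases", {
  chain <- toy_model("chain")
  fd <- fba(chain, "biomass")
  expect_identical(fd$status, "optimal")
  expect_equal(unname(fd$objective_values), 10, tolerance = 1e-9)
  expect_lte(max(abs(chain$S %*% fd$fluxes)), 1e-6)

  # all bounds zero: the origin is the only feasible point
  closed <- chain
  closed$upper_bounds[] <- 0
  fd0 <- fba(closed, "biomass")
  expect_equal(unname(fd0$objective_values), 0)
  expect_equal(unname(fd0$fluxes), c(0, 0, 0))

  # doubling all bounds doubles the optimum (LP positive homogeneity)
  doubled <- chain
  doubled$upper_bounds <- 2 * chain$upper_bounds
  expect_equal(unname(fba(doubled, "biomass")$objective_values), 20,
               tolerance = 1e-9)
})

test_that("lexicographic FBA fixes levels in priority order", {
  chain <- toy_model("chain")
  fd <- lexicographic_fba(chain, c("biomass", "product"))
  expect_equal(unname(fd$objective_values), c(10, 0), tolerance = 1e-6)

  branch <- toy_model("branch")
  fd2 <- lexicographic_fba(branch, c("biomass", "product"))
  expect_equal(unname(fd2$objective_values), c(6, 4), tolerance = 1e-6)

  # a single level reduces to plain FBA
  expect_equal(unname(lexicographic_fba(chain, "biomass")$objective_values),
               unname(fba(chain, "biomass")$objective_values))

  # level-1 optimum always equals the single-level optimum
  expect_equal(fd2$objective_values[["biomass"]],
               unname(fba(branch, "biomass")$objective_values),
               tolerance = 1e-6)

  expect_error(lexicographic_fba(chain, c("a", "b", "c", "d")), "between 1 and 3")
})

test_that("lexicographic FBA matches exhaustive vertex enumeration", {
  for (variant in c("chain", "branch")) {
    m <- toy_model(variant)
    for (objs in list("biomass", c("biomass", "product"),
                      c("product", "biomass"),
                      c("biomass", "product", "uptake"))) {
      got <- unname(lexicographic_fba(m, objs)$objective_values)
      want <- lex_vertex_oracle(m, objs)
      expect_equal(got, want, tolerance = 1e-6,
                   info = paste(variant, paste(objs, collapse = ">")))
    }
  }
})

test_that("infeasibility after fixing names the failing level", {
  m <- toy_model("chain")
  m$lower_bounds["product"] <- 20  # can never carry 20 with uptake capped at 10
  expect_error(lexicographic_fba(m, c("biomass", "product")),
               "level 1.*infeasible")
})

test_that("pareto_front returns exactly the non-dominated subset", {
  pts <- rbind(c(1, 1), c(2, 0), c(0, 2), c(0.5, 0.5))
  front <- pareto_front(pts)
  expect_equal(front, rbind(c(0, 2), c(1, 1), c(2, 0)))

  expect_equal(pareto_front(rbind(c(3, 4), c(3, 4))), rbind(c(3, 4)))
  single <- matrix(c(1, 2), 1)
  expect_equal(pareto_front(single), single)
  empty <- matrix(numeric(0), 0, 2)
  expect_identical(nrow(pareto_front(empty)), 0L)

  # brute-force dominance property on random clouds
  set.seed(11)
  for (i in 1:10) {
    pts <- matrix(stats::runif(60), ncol = 3)
    front <- pareto_front(pts)
    dominated <- function(p, q) all(q >= p) && any(q > p)
    for (r in seq_len(nrow(front)))
      for (s in seq_len(nrow(front)))
        if (r != s) expect_false(dominated(front[r, ], front[s, ]))
    excluded <- pts[!duplicated(pts), , drop = FALSE]
    excluded <- excluded[!apply(excluded, 1, function(p)
      any(apply(front, 1, function(f) all(f == p)))), , drop = FALSE]
    for (r in seq_len(nrow(excluded)))
      expect_true(any(apply(front, 1, dominated, p = excluded[r, ])))
  }
})

test_that("flux distributions export as two-column text", {
  fd <- fba(toy_model("chain"), "biomass")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fluxes(fd, path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("reaction_id", "flux"))
  expect_equal(tab$flux, unname(fd$fluxes))
})

test_that("the LP solver agrees with vertex enumeration on random networks", {
  set.seed(19)
  for (i in 1:15) {
    m_mets <- sample(1:3, 1)
    n_rxns <- sample(3:6, 1)
    S <- matrix(sample(c(-1, 0, 1), m_mets * n_rxns, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)), m_mets, n_rxns)
    lb <- ifelse(runif(n_rxns) < 0.3, -round(runif(n_rxns, 1, 5), 1), 0)
    ub <- round(runif(n_rxns, 0.5, 10), 1)
    obj <- as.numeric(runif(n_rxns) < 0.5)
    if (all(obj == 0)) obj[1] <- 1
    sol <- fuseflux:::solve_lp(obj, S, lb, ub)
    V <- enumerate_vertices(S, lb, ub)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective, max(V %*% obj), tolerance = 1e-8,
                 info = paste("case", i))
  }
})
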