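chain_json <- function(path) {
  write_model(toy_model("chain"), path)
  path
}

test_that("the JSON dialect round-trips field for field", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- toy_model("chain")
  write_model(m, path)
  m2 <- read_model(path, format = "json")
  expect_identical(m2$metabolite_ids, m$metabolite_ids)
  expect_identical(m2$reaction_ids, m$reaction_ids)
  expect_equal(m2$S, m$S)
  expect_equal(m2$lower_bounds, m$lower_bounds)
  expect_equal(m2$upper_bounds, m$upper_bounds)
  expect_identical(lapply(m2$gpr, format_gpr), lapply(m$gpr, format_gpr))
  expect_identical(sort(m2$gene_ids), sort(m$gene_ids))
  # toy 3-reaction fixture has the documented shape
  expect_identical(dim(m2$S), c(1L, 3L))
})

test_that("model invariants are enforced by the constructor", {
  S <- matrix(c(1, -1), 1, dimnames = list("M", c("a", "b")))
  expect_error(metabolic_model(S, c(0, 5), c(10, 1)), "lower bound exceeds")
  expect_error(metabolic_model(rbind(S, S), c(0, 0), c(1, 1),
                               metabolite_ids = c("M", "M"),
                               reaction_ids = c("a", "b")),
               "duplicate metabolite")
  expect_error(metabolic_model(S, c(0, 0), c(1, 1),
                               gpr = list(a = "gX"), gene_ids = "gY"),
               "absent from gene_ids")
})

test_that("SBML-FBC models parse with bounds and gene associations", {
  path <- test_path("fixtures", "synthetic_toy.sbml.xml")
  m <- read_model(path, format = "sbml")
  expect_identical(length(m$metabolite_ids), 1L)
  expect_identical(length(m$reaction_ids), 3L)
  g <- m$gpr[["AAT"]]
  expect_identical(unclass(g)$op, "or")
  expect_setequal(gpr_genes(g), c("aspC", "tyrB"))
  expect_equal(unname(m$upper_bounds["uptake"]), 10)
  # bounds absent from the file fall back to the configured defaults
  expect_equal(unname(m$lower_bounds["rev_free"]), -1000)
  expect_equal(unname(m$upper_bounds["rev_free"]), 1000)
})

test_that("augment_model appends reactions, replaces GPRs, and is idempotent", {
  m <- toy_model("chain")
  # empty tables leave the model unchanged
  m0 <- augment_model(m, NULL, NULL)
  expect_equal(m0$S, m$S)

  upd <- data.frame(reaction_id = "uptake", old_gpr = "gU", new_gpr = "gU OR prpC")
  add <- data.frame(reaction_id = "side", stoichiometry = "M:-1",
                    lower_bound = 0, upper_bound = 2, gpr = "gS")
  m1 <- augment_model(m, add, upd)
  expect_identical(format_gpr(m1$gpr$uptake), "gU OR prpC")
  # one new reaction consuming an existing metabolite: n + 1, m unchanged
  expect_identical(dim(m1$S), dim(m$S) + c(0L, 1L))
  expect_equal(unname(m1$S["M", "side"]), -1)
  # untouched content is preserved
  expect_equal(m1$S[, m$reaction_ids, drop = FALSE], m$S)
  expect_equal(m1$upper_bounds[m$reaction_ids], m$upper_bounds)
  # the zero flux vector stays balanced after augmentation
  expect_equal(max(abs(m1$S %*% numeric(ncol(m1$S)))), 0)

  # re-applying the same tables is a no-op
  m2 <- augment_model(m1, add, upd)
  expect_equal(m2$S, m1$S)
  expect_identical(format_gpr(m2$gpr$uptake), format_gpr(m1$gpr$uptake))

  # conflicting duplicate and unknown update are errors
  add_conflict <- transform(add, upper_bound = 99)
  expect_error(augment_model(m1, add_conflict), "duplicate addition")
  expect_error(augment_model(m, gpr_updates = data.frame(reaction_id = "nope",
                                                         new_gpr = "g1")),
               "unknown reaction")
})

test_that("augmentation with a new metabolite adds a row", {
  m <- toy_model("chain")
  add <- data.frame(reaction_id = "exo", stoichiometry = "M:-1, X:1",
                    lower_bound = 0, upper_bound = 5, gpr = NA)
  m1 <- augment_model(m, add)
  expect_identical(dim(m1$S), dim(m$S) + c(1L, 1L))
  expect_true("X" %in% m1$metabolite_ids)
})

test_that("addition and GPR-update tables read from TSV", {
  add_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tstoichiometry\tlower_bound\tupper_bound\tgpr",
               "side\tM:-1\t0\t2\tgS"), add_path)
  add <- read_reaction_additions(add_path)
  expect_identical(add$reaction_id, "side")

  upd_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\told_gpr\tnew_gpr",
               "biomass\tgB1 AND gB2\tgB1 AND gB2 AND gB3"), upd_path)
  upd <- read_gpr_updates(upd_path)
  m1 <- augment_model(toy_model("chain"), add, upd)
  expect_identical(format_gpr(m1$gpr$biomass), "gB1 AND gB2 AND gB3")

  bad_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tnew_gpr", "biomass\tg1 AND"), bad_path)
  expect_error(read_gpr_updates(bad_path), "unexpected end")
})
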