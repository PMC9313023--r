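test_that("generated proteins re-derive their intended class and validate", {
  ds <- generate_dataset("caid_like", seed = 3)
  expect_true(is_probe <- all(vapply(ds$proteins, inherits, logical(1),
                                     "annotated_protein")))
  derived <- classify_idps(ds$proteins)
  expect_equal(derived$class[match(ds$classes$protein_id, derived$protein_id)],
               ds$classes$class)
  # serialised output passes the readers' validation
  ref <- tempfile(); bnd <- tempfile()
  write_reference(ds$proteins, ref)
  write_reference(ds$proteins, bnd, track = "binding")
  back <- merge_binding(read_reference(ref),
                        read_reference(bnd, track = "binding"))
  expect_equal(length(back), length(ds$proteins))
  expect_identical(back$SYN0001$disorder, ds$proteins$SYN0001$disorder)
})

test_that("same seed gives byte-identical datasets; different seeds differ", {
  a <- generate_dataset("null", seed = 5)
  b <- generate_dataset("null", seed = 5)
  c <- generate_dataset("null", seed = 6)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$tracks$mediocre$scores, b$tracks$mediocre$scores)
  expect_false(identical(a$proteins, c$proteins))
})

test_that("empirical residue composition converges to the configured vector", {
  cfg <- synthetic_config(
    n_per_class = c(high_nonbinding = 60L),
    class_params = list(high_nonbinding = list(len = c(800L, 1200L),
                                               content = c(0.45, 0.65))),
    seed = 12)
  ds <- generate_reference(cfg)
  pool <- residue_pool(ds$proteins, "disorder")
  freq <- pool / sum(pool)
  expect_gt(sum(pool), 2e4)
  expect_lt(max(abs(freq - DISORDER_COMPOSITION)), 0.012)
})

test_that("injected enrichment factors shift the disorder composition", {
  cfg <- synthetic_config(
    n_per_class = c(high_nonbinding = 40L),
    enrichment = list(P = 2.0),
    class_params = list(high_nonbinding = list(len = c(500L, 800L))),
    seed = 2)
  ds <- generate_reference(cfg)
  pool <- residue_pool(ds$proteins, "disorder")
  expected <- local({
    f <- DISORDER_COMPOSITION; f["P"] <- f["P"] * 2; f / sum(f)
  })
  expect_equal(unname(pool[["P"]] / sum(pool)), unname(expected[["P"]]),
               tolerance = 0.1)
})

test_that("binormal score tracks hit their target AUC", {
  cfg <- synthetic_config(
    n_per_class = c(high_nonbinding = 40L),
    class_params = list(high_nonbinding = list(len = c(200L, 300L))),
    seed = 31)
  ds <- generate_reference(cfg)
  for (target in c(0.5, 0.8)) {
    tr <- generate_predictions(ds$proteins, ds$classes, "t",
                               c(high_nonbinding = target), seed = 7)
    ev <- evaluate(tr, ds$proteins)
    expect_lt(abs(ev$auc - target), 0.03)
  }
  # separation limit
  tr1 <- generate_predictions(ds$proteins, ds$classes, "perfect",
                              c(high_nonbinding = 1.0), seed = 7)
  expect_equal(evaluate(tr1, ds$proteins)$auc, 1.0)
})

test_that("profiles with unknown classes or invalid targets are rejected", {
  ds <- generate_reference(synthetic_preset("null", seed = 1))
  expect_error(generate_predictions(ds$proteins, ds$classes, "x",
                                    c(not_a_class = 0.8)), "unknown class")
  expect_error(generate_predictions(ds$proteins, ds$classes, "x",
                                    c(high_binding = 0.3)), "0.5")
  expect_error(generate_predictions(ds$proteins, ds$classes, "x",
                                    c(high_binding = 0.9)), "no target AUC")
  expect_error(synthetic_preset("bogus"), "available")
  # infeasible architecture is caught at config validation
  expect_error(synthetic_config(
    n_per_class = c(low_short = 5L),
    class_params = list(low_short = list(len = c(50L, 60L), n_idr = c(2L, 2L)))),
    "exceed")
})

test_that("caid_like length statistics loosely match the reference benchmark", {
  ds <- generate_dataset("caid_like", seed = 1)
  s <- region_summary(ds$proteins)
  overall <- s$median_length[s$set == "complete"]
  short <- s$median_length[s$set == "short"]
  expect_lt(abs(overall - 34) / 34, 0.3)
  expect_lt(abs(short - 12) / 12, 0.3)
})
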