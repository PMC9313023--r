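test_that("residue pools count selected residues and skip non-standard letters", {
  p1 <- make_protein("A", "PPKEX", "11110")
  p2 <- make_protein("B", "GGSAA", "11000")
  prots <- list(A = p1, B = p2)
  pool <- residue_pool(prots, "disorder")
  expect_equal(pool[["P"]], 2L)
  expect_equal(pool[["K"]], 1L)
  expect_equal(pool[["G"]], 2L)
  expect_equal(sum(pool), 6L)           # X not counted
  expect_equal(attr(pool, "n_selected"), 6L)

  bg <- residue_pool(prots, "nondisordered")
  expect_equal(sum(bg), 3L)                 # the X residue is excluded
  expect_equal(attr(bg, "n_selected"), 4L)  # ...but was selected

  expect_error(build_pools(prots, "binding", "nondisordered"),
               "no standard residues")
  expect_error(build_pools(prots, "disorder", "disorder"), "overlap")
})

test_that("enrichment is the relative frequency difference, bounded below by -1", {
  s <- setNames(rep(0L, 20), AA20); b <- s
  s["P"] <- 10L; s["A"] <- 90L
  b["P"] <- 5L; b["A"] <- 75L; b["W"] <- 20L
  expect_equal(enrichment(s, b, "P"), 1.0)
  expect_equal(enrichment(s, b, "W"), -1.0)
  expect_error(enrichment(s, s, "W"), "undefined")

  # identical pools -> all zero; scaling either pool leaves it unchanged
  full <- setNames(seq(10L, 200L, by = 10L), AA20)
  expect_equal(unname(enrichment(full, full)), rep(0, 20))
  expect_equal(enrichment(full, full * 7L), enrichment(full, full))
  expect_true(all(enrichment(s + 1L, b + 1L) >= -1))
})

test_that("swapping sample and background negates the deviation, keeps p-values", {
  set.seed(5)
  s <- setNames(as.integer(rmultinom(1, 4000, rep(1, 20))), AA20)
  b <- setNames(as.integer(rmultinom(1, 6000, c(rep(1, 10), rep(1.4, 10)))), AA20)
  f1 <- compute_scale(s, b, n_resamples = 400, seed = 9)
  f2 <- compute_scale(b, s, n_resamples = 400, seed = 9)
  dev1 <- f1$freq_sample - f1$freq_background
  dev2 <- f2$freq_sample - f2$freq_background
  expect_equal(dev1, -dev2)
  # the permutation null is symmetric: p-values agree up to resampling noise
  expect_true(all(abs(f1$p_value - f2$p_value) < 0.08))
})

test_that("compute_scale is reproducible given a seed and enforces call semantics", {
  set.seed(11)
  s <- setNames(as.integer(rmultinom(1, 3000, rep(1, 20))), AA20)
  b <- setNames(as.integer(rmultinom(1, 3000, rep(1, 20))), AA20)
  a1 <- compute_scale(s, b, n_resamples = 300, seed = 42)
  a2 <- compute_scale(s, b, n_resamples = 300, seed = 42)
  expect_identical(a1$values, a2$values)
  expect_identical(a1$p_value, a2$p_value)

  expect_true(all((a1$significance == "neutral") == (a1$p_value >= 0.05)))
  expect_true(all(a1$values[a1$significance == "enriched"] > 0))
  expect_true(all(a1$values[a1$significance == "depleted"] < 0))
  expect_true(all(a1$p_value >= 0 & a1$p_value <= 1))
})

test_that("a doubled proline frequency is called enriched with p < 0.05", {
  comp <- rep(1 / 20, 20); names(comp) <- AA20
  comp2 <- comp; comp2["P"] <- comp2["P"] * 2; comp2 <- comp2 / sum(comp2)
  set.seed(21)
  s <- setNames(as.integer(rmultinom(1, 10000, comp2[AA20])), AA20)
  b <- setNames(as.integer(rmultinom(1, 10000, comp[AA20])), AA20)
  sc <- compute_scale(s, b, n_resamples = 1000, seed = 3)
  expect_equal(unname(sc$significance[["P"]]), "enriched")
  expect_lt(sc$p_value[["P"]], 0.05)
  expect_gt(sc$values[["P"]], 0)
})
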