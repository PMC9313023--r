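test_that("metric primitives match hand-derived values", {
  # perfect separation
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  # Mann-Whitney pair counting: 3 of 4 pairs correctly ordered
  expect_equal(auc_score(c(0.9, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  # reversal and monotone invariance
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  expect_equal(auc_score(qlogis(s), y), auc_score(s, y))
  expect_equal(auc_score(-s, y), 1 - auc_score(s, y))

  # confusion TP=2 FP=1 FN=1 TN=6: MCC = 11/21, F1 = 2/3
  calls <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  labs <-  c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(mcc_score(calls, labs), 11 / 21)
  expect_equal(f1_score(calls, labs), 2 / 3)
  expect_equal(mcc_score(rep(1, 4), c(1, 1, 0, 0)), 0)  # degenerate marginal

  # AUPR: perfect ranking gives 1; a known 4-point case by hand
  expect_equal(aupr_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  # scores .9(+) .7(-) .5(+) .3(-): prec at recalls .5, 1 -> 1, 2/3
  expect_equal(aupr_score(c(0.9, 0.7, 0.5, 0.3), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
})

test_that("rank-statistic AUC agrees with an established ROC implementation", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    y <- rbinom(n, 1, 0.35)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
    expect_equal(auc_score(s, y), ref, tolerance = 1e-12)
  }
})

test_that("evaluate pools residues, drops unannotated ones, errors on one class", {
  prots <- list(
    A = make_protein("A", random_seq(6), "1100--"),
    B = make_protein("B", random_seq(4), "0011")
  )
  tr <- prediction_track("t",
    scores = list(A = c(0.9, 0.8, 0.2, 0.6, 0.5, 0.5), B = c(0.1, 0.3, 0.7, 0.95)),
    calls = list(A = c(1L, 1L, 0L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L)))
  ev <- evaluate(tr, prots)
  expect_equal(ev$n_residues, 8)   # the two unannotated residues are excluded
  expect_equal(ev$n_positive, 4)
  expect_equal(ev$auc,
               oracle_auc(c(0.9, 0.8, 0.2, 0.6, 0.1, 0.3, 0.7, 0.95),
                          c(1, 1, 0, 0, 0, 0, 1, 1)))
  # calls kept: A (1,1,0,1), B (0,0,1,1) vs labels A (1,1,0,0), B (0,0,1,1)
  # -> TP=4, FP=1, FN=0, TN=3
  expect_equal(ev$mcc, 12 / sqrt(240))
  expect_equal(ev$f1, 8 / 9)

  allpos <- list(C = make_protein("C", random_seq(3), "111"))
  trc <- prediction_track("t", list(C = c(.1, .2, .3)))
  expect_error(evaluate(trc, allpos, subset_name = "weird"), "weird")
})

test_that("per-class evaluation separates specialist performance", {
  ds <- generate_dataset("class_specialists", seed = 5)
  tab <- evaluate_by_class(ds$tracks[c("spec_fully_disordered", "spec_low_short")],
                           ds$proteins, ds$classes)
  fd <- tab[tab$predictor == "spec_fully_disordered", ]
  expect_gt(fd$auc[fd$subset == "fully_disordered"], 0.85)
  expect_lt(fd$auc[fd$subset == "low_short"], 0.7)
  # single-class rows are reported with NA metrics, not dropped
  expect_true(all(c("all", "fully_disordered") %in% fd$subset))
  # residue partition: class rows sum to the pooled total
  one <- tab[tab$predictor == "spec_low_short" & tab$subset != "all", ]
  expect_equal(sum(one$n_residues, na.rm = TRUE),
               tab$n_residues[tab$predictor == "spec_low_short" &
                              tab$subset == "all"])
})

test_that("identical tracks are never significant; results reproducible by seed", {
  ds <- generate_dataset("null", seed = 8)
  tr <- ds$tracks$mediocre
  bc <- bootstrap_compare(tr, tr, ds$proteins, n_iter = 20, seed = 4)
  expect_equal(bc$test_used, "none")
  expect_equal(bc$p_value, 1)
  expect_true(all(bc$values_a == bc$values_b))

  tr2 <- generate_predictions(ds$proteins, ds$classes, "other",
                              c(high_binding = 0.6, high_nonbinding = 0.6),
                              seed = 99)
  b1 <- bootstrap_compare(tr, tr2, ds$proteins, n_iter = 30, seed = 7)
  b2 <- bootstrap_compare(tr, tr2, ds$proteins, n_iter = 30, seed = 7)
  expect_identical(b1$values_a, b2$values_a)
  expect_identical(b1$p_value, b2$p_value)
  # symmetry of the paired test
  b3 <- bootstrap_compare(tr2, tr, ds$proteins, n_iter = 30, seed = 7)
  expect_equal(b1$p_value, b3$p_value)
  expect_true(b1$test_used %in% c("t_test", "wilcoxon"))
})

test_that("a real AUC gap is detected as significant", {
  ds <- generate_dataset("null", seed = 15)
  good <- generate_predictions(ds$proteins, ds$classes, "good",
                               c(high_binding = 0.85, high_nonbinding = 0.85),
                               seed = 1)
  poor <- generate_predictions(ds$proteins, ds$classes, "poor",
                               c(high_binding = 0.7, high_nonbinding = 0.7),
                               seed = 2)
  bc <- bootstrap_compare(good, poor, ds$proteins, n_iter = 50, seed = 3)
  expect_lt(bc$p_value, 0.05)
  expect_gt(mean(bc$values_a), mean(bc$values_b))
})

test_that("min-max normalisation and identity routing reproduce the routed track", {
  ds <- generate_dataset("class_specialists", seed = 23)
  x <- ds$tracks[[1]]
  routing <- meta_routing(
    fully_disordered = x$name, low_short = x$name, low_binding_long = x$name,
    low_nonbinding_long = x$name, high_binding = x$name, high_nonbinding = x$name)
  meta <- assemble_meta(ds$tracks, routing, ds$classes, ds$proteins)
  em <- evaluate(meta, ds$proteins)
  ex <- evaluate(x, ds$proteins)
  expect_equal(em$auc, ex$auc)
  expect_equal(em$aupr, ex$aupr)
  expect_equal(em$mcc, ex$mcc)      # native calls are passed through
  expect_equal(em$f1, ex$f1)

  # direct formula check
  tr <- prediction_track("lin", list(P = c(2, 4, 6)))
  prot <- list(P = make_protein("P", random_seq(3), "110"))
  cls <- data.frame(protein_id = "P", class = "high_nonbinding")
  r <- meta_routing(fully_disordered = "lin", low_short = "lin",
                    low_binding_long = "lin", low_nonbinding_long = "lin",
                    high_binding = "lin", high_nonbinding = "lin")
  m <- assemble_meta(list(tr), r, cls, prot)
  expect_equal(m$scores$P, c(0, 0.5, 1))
})

test_that("constant-score predictors are rejected by min-max normalisation", {
  prot <- list(P = make_protein("P", random_seq(3), "110"))
  cls <- data.frame(protein_id = "P", class = "high_nonbinding")
  r <- meta_routing(fully_disordered = "flat", low_short = "flat",
                    low_binding_long = "flat", low_nonbinding_long = "flat",
                    high_binding = "flat", high_nonbinding = "flat")
  const <- prediction_track("flat", list(P = c(1, 1, 1)))
  expect_error(assemble_meta(list(const), r, cls, prot), "constant scores")
})

test_that("routing must cover every class with known predictors", {
  expect_error(meta_routing(fully_disordered = "a"), "missing")
  prot <- list(P = make_protein("P", random_seq(3), "110"))
  cls <- data.frame(protein_id = "P", class = "high_nonbinding")
  r <- meta_routing(fully_disordered = "ghost", low_short = "ghost",
                    low_binding_long = "ghost", low_nonbinding_long = "ghost",
                    high_binding = "ghost", high_nonbinding = "ghost")
  tr <- prediction_track("real", list(P = c(1, 2, 3)))
  expect_error(assemble_meta(list(tr), r, cls, prot), "unknown predictor")
})
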