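# Per-residue scoring of predictor tracks against reference annotations,
# bootstrap significance comparison, and the class-routed meta-predictor.

#' Area under the ROC curve (rank statistic, ties averaged)
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop_("AUC undefined: need both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds sweep the distinct score values from high to low; tied scores
#' enter together. The curve is integrated as
#' `sum((recall_i - recall_{i-1}) * precision_i)`.
#'
#' @inheritParams auc_score
#' @return AUPR in `[0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L || sum(labels == 0L) == 0L)
    stop_("AUPR undefined: need both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

# Confusion counts from binary calls.
confusion <- function(calls, labels) {
  calls <- as.integer(calls); labels <- as.integer(labels)
  c(tp = sum(calls == 1L & labels == 1L),
    fp = sum(calls == 1L & labels == 0L),
    fn = sum(calls == 0L & labels == 1L),
    tn = sum(calls == 0L & labels == 0L))
}

#' Matthews correlation coefficient from binary calls
#'
#' Returns 0 when any marginal is empty (the usual degenerate-denominator
#' convention).
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 reference labels.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(calls, labels) {
  k <- confusion(calls, labels)
  denom <- sqrt(prod(c(k["tp"] + k["fp"], k["tp"] + k["fn"],
                       k["tn"] + k["fp"], k["tn"] + k["fn"])))
  if (denom == 0) return(0)
  unname((k["tp"] * k["tn"] - k["fp"] * k["fn"]) / denom)
}

#' F1 score from binary calls
#'
#' @inheritParams mcc_score
#' @return F1 in `[0, 1]` (0 when no positive calls and no positives).
#' @export
f1_score <- function(calls, labels) {
  k <- confusion(calls, labels)
  denom <- 2 * k["tp"] + k["fp"] + k["fn"]
  if (denom == 0) return(0)
  unname(2 * k["tp"] / denom)
}

# Pool annotated residues of `subset` proteins: labels from the disorder
# track (NA dropped), scores and calls aligned from the prediction track.
pool_residues <- function(track, proteins, subset = NULL, threshold = 0.5) {
  ids <- subset %||% names(proteins)
  miss <- setdiff(ids, names(track$scores))
  if (length(miss))
    stop_("track '%s' does not cover protein(s): %s", track$name,
          paste(utils::head(miss, 3), collapse = ", "))
  lab <- sc <- cl <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    p <- proteins[[id]]
    if (is.null(p)) stop_("unknown protein id '%s'", id)
    s <- track$scores[[id]]
    if (length(s) != nchar(p$sequence))
      stop_("track '%s', protein '%s': %d scores for %d residues",
            track$name, id, length(s), nchar(p$sequence))
    keep <- !is.na(p$disorder)
    lab[[i]] <- p$disorder[keep]
    sc[[i]] <- s[keep]
    cl[[i]] <- if (!is.null(track$calls)) track$calls[[id]][keep]
               else as.integer(s[keep] >= threshold)
  }
  list(labels = unlist(lab), scores = unlist(sc), calls = unlist(cl))
}

#' Evaluate a prediction track on a protein subset
#'
#' Residues are pooled across the subset's proteins (not averaged per
#' protein); the disordered state is the positive class and unannotated
#' residues are excluded. MCC and F1 use the predictor's native binary calls
#' when present, otherwise scores thresholded at `threshold`.
#'
#' @param track A [prediction_track].
#' @param proteins Named list of [annotated_protein].
#' @param subset Optional character vector of protein ids (default: all).
#' @param subset_name Label stored in the result row.
#' @param threshold Score threshold replacing absent native calls.
#' @return One-row data frame: `predictor`, `subset`, `auc`, `aupr`, `mcc`,
#'   `f1`, `n_residues`, `n_positive`.
#' @export
evaluate <- function(track, proteins, subset = NULL, subset_name = "all",
                     threshold = 0.5) {
  assert_protein_list(proteins)
  pr <- pool_residues(track, proteins, subset, threshold)
  np <- sum(pr$labels == 1L)
  if (np == 0L || np == length(pr$labels))
    stop_("subset '%s' has a single annotation class: metrics undefined",
          subset_name)
  data.frame(predictor = track$name, subset = subset_name,
             auc = auc_score(pr$scores, pr$labels),
             aupr = aupr_score(pr$scores, pr$labels),
             mcc = mcc_score(pr$calls, pr$labels),
             f1 = f1_score(pr$calls, pr$labels),
             n_residues = length(pr$labels), n_positive = np,
             stringsAsFactors = FALSE)
}

#' Evaluate predictors on the whole dataset and per disorder class
#'
#' @param tracks List of [prediction_track] objects.
#' @param proteins Named list of [annotated_protein].
#' @param classes [classify_idps()] table (computed when `NULL`).
#' @return Data frame with one row per (predictor, subset); subsets are
#'   `"all"` plus every class present. Classes whose pooled residues contain
#'   a single annotation class get `NA` metrics.
#' @export
evaluate_by_class <- function(tracks, proteins, classes = NULL) {
  if (inherits(tracks, "prediction_track")) tracks <- list(tracks)
  if (is.null(classes)) classes <- classify_idps(proteins)
  rows <- list()
  for (tr in tracks) {
    rows[[length(rows) + 1L]] <- evaluate(tr, proteins)
    for (cls in intersect(IDP_CLASSES, unique(classes$class))) {
      ids <- classes$protein_id[classes$class == cls]
      row <- tryCatch(evaluate(tr, proteins, subset = ids, subset_name = cls),
                      error = function(e) {
                        data.frame(predictor = tr$name, subset = cls,
                                   auc = NA_real_, aupr = NA_real_,
                                   mcc = NA_real_, f1 = NA_real_,
                                   n_residues = NA_integer_,
                                   n_positive = NA_integer_,
                                   stringsAsFactors = FALSE)
                      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bootstrap significance comparison of two predictors
#'
#' Repeatedly draws `floor(fraction * N)` proteins (without replacement by
#' default, i.e. a repeated half-split), evaluates the chosen metric for both
#' tracks on each drawn set, and tests the paired per-iteration values:
#' Anderson-Darling normality of the differences at p = 0.05 decides between
#' a paired Student t-test and the Wilcoxon signed-rank test. Both tracks see
#' identical draws, so the comparison is paired by construction. Iterations
#' on which the metric is undefined (single-class sample) are redrawn, with a
#' retry cap.
#'
#' Note: this protocol quantifies how robust the *observed* performance gap
#' on the given dataset is to resampling the protein set; it is not a
#' calibrated test of equality of the predictors' population-level accuracy
#' (its null rejection rate exceeds the nominal level when two equally good
#' predictors show a nonzero realised gap on the fixed dataset).
#'
#' @param track_a,track_b [prediction_track] objects covering the proteins.
#' @param proteins Named list of [annotated_protein].
#' @param metric One of `"auc"`, `"aupr"`, `"mcc"`, `"f1"`.
#' @param n_iter Number of resampling iterations (default 100).
#' @param fraction Fraction of proteins drawn per iteration (default 0.5).
#' @param replace Draw with replacement instead of the half-split.
#' @param seed Optional seed (result reproducible given the seed).
#' @param threshold Score threshold replacing absent native calls.
#' @return Object of class `bootstrap_comparison`: metric name, per-iteration
#'   values for both methods, the normality p-value, the test used
#'   (`"t_test"`, `"wilcoxon"` or `"none"` for identical values) and its
#'   p-value.
#' @export
bootstrap_compare <- function(track_a, track_b, proteins, metric = "auc",
                              n_iter = 100L, fraction = 0.5, replace = FALSE,
                              seed = NULL, threshold = 0.5) {
  metric <- match.arg(metric, c("auc", "aupr", "mcc", "f1"))
  if (n_iter < 2L) stop_("n_iter must be >= 2")
  if (fraction <= 0 || fraction > 1) stop_("fraction must be in (0, 1]")
  assert_protein_list(proteins)
  ids <- names(proteins)
  n_draw <- max(1L, floor(fraction * length(ids)))
  eval_one <- function(track, drawn) {
    pr <- pool_residues(track, proteins, drawn, threshold)
    if (!any(pr$labels == 1L) || !any(pr$labels == 0L)) return(NA_real_)
    switch(metric,
           auc = auc_score(pr$scores, pr$labels),
           aupr = aupr_score(pr$scores, pr$labels),
           mcc = mcc_score(pr$calls, pr$labels),
           f1 = f1_score(pr$calls, pr$labels))
  }
  res <- with_seed(seed, {
    va <- vb <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      ok <- FALSE
      for (try in 1:50) {
        drawn <- sample(ids, n_draw, replace = replace)
        a <- eval_one(track_a, drawn)
        b <- eval_one(track_b, drawn)
        if (!is.na(a) && !is.na(b)) { ok <- TRUE; break }
      }
      if (!ok) stop_("metric undefined in 50 consecutive redraws at iteration %d", it)
      va[it] <- a; vb[it] <- b
    }
    list(va = va, vb = vb)
  })
  d <- res$va - res$vb
  if (stats::sd(d) == 0) {
    test_used <- "none"; p_value <- 1; normality_p <- NA_real_
  } else {
    normality_p <- nortest::ad.test(d)$p.value
    if (normality_p >= 0.05) {
      test_used <- "t_test"
      p_value <- stats::t.test(d)$p.value
    } else {
      test_used <- "wilcoxon"
      p_value <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    }
  }
  structure(list(metric = metric, method_a = track_a$name,
                 method_b = track_b$name, n_iter = as.integer(n_iter),
                 sample_fraction = fraction, replace = replace,
                 values_a = res$va, values_b = res$vb,
                 normality_p = normality_p, test_used = test_used,
                 p_value = p_value, seed = seed),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("<bootstrap_comparison> %s: %s (mean %.4f) vs %s (mean %.4f)\n",
              x$metric, x$method_a, mean(x$values_a),
              x$method_b, mean(x$values_b)))
  cat(sprintf("  %d iterations of %.0f%% draws; test: %s, p = %.4g\n",
              x$n_iter, 100 * x$sample_fraction, x$test_used, x$p_value))
  invisible(x)
}

#' Validate a class-to-predictor routing table
#'
#' @param ... Named arguments `class = "predictor"`; every one of the six
#'   classes must be mapped, and `unassigned` gets `default` unless mapped
#'   explicitly.
#' @param default Predictor used for unassigned proteins.
#' @return Named character vector over all seven class labels.
#' @export
meta_routing <- function(..., default = NULL) {
  r <- c(...)
  need <- setdiff(IDP_CLASSES, "unassigned")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop_("routing must map every class; missing: %s", paste(miss, collapse = ", "))
  if (!"unassigned" %in% names(r)) {
    if (is.null(default)) default <- r[[1]]
    r <- c(r, unassigned = default)
  }
  r[IDP_CLASSES]
}

#' Assemble the class-routed meta-predictor
#'
#' Each predictor's scores are min-max normalised over all its residues in
#' the dataset, `(s - min) / (max - min)`; each protein then receives the
#' normalised scores — and the native binary calls — of the predictor routed
#' for the protein's disorder class.
#'
#' @param tracks List of [prediction_track] objects (the component
#'   predictors).
#' @param routing Named character vector class -> predictor name (see
#'   [meta_routing()]).
#' @param classes [classify_idps()] table covering every protein.
#' @param proteins Named list of [annotated_protein].
#' @param name Name of the assembled track.
#' @return A [prediction_track] with normalised scores and routed calls.
#' @export
assemble_meta <- function(tracks, routing, classes, proteins, name = "meta") {
  assert_protein_list(proteins)
  if (inherits(tracks, "prediction_track")) tracks <- list(tracks)
  tnames <- vapply(tracks, `[[`, character(1), "name")
  names(tracks) <- tnames
  used <- unique(routing[intersect(names(routing), unique(classes$class))])
  miss <- setdiff(unname(routing), tnames)
  if (length(miss))
    stop_("routing names unknown predictor(s): %s", paste(miss, collapse = ", "))
  cls_of <- stats::setNames(classes$class, classes$protein_id)
  if (!all(names(proteins) %in% names(cls_of)))
    stop_("classes table does not cover every protein")
  # per-predictor dataset-wide min-max
  norm <- list()
  for (nm in unique(unname(routing))) {
    allsc <- unlist(tracks[[nm]]$scores[names(proteins)])
    mn <- min(allsc); mx <- max(allsc)
    if (mx == mn) stop_("predictor '%s' has constant scores: min-max undefined", nm)
    norm[[nm]] <- c(mn = mn, mx = mx)
  }
  scores <- calls <- list()
  any_calls <- FALSE
  for (id in names(proteins)) {
    cls <- cls_of[[id]]
    nm <- routing[[cls]]
    if (is.null(nm) || is.na(nm)) stop_("no routing for class '%s'", cls)
    s <- tracks[[nm]]$scores[[id]]
    if (is.null(s)) stop_("predictor '%s' does not cover protein '%s'", nm, id)
    mm <- norm[[nm]]
    scores[[id]] <- (s - mm[["mn"]]) / (mm[["mx"]] - mm[["mn"]])
    if (!is.null(tracks[[nm]]$calls)) {
      calls[[id]] <- tracks[[nm]]$calls[[id]]
      any_calls <- TRUE
    } else {
      calls[[id]] <- as.integer(scores[[id]] >= 0.5)
    }
  }
  prediction_track(name, scores, calls)
}
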