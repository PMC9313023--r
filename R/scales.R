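# Comparison of propensity scales: Kendall rank correlation matrices and the
# accuracy-vs-bias-agreement Pearson correlation.

#' Kendall rank correlation between two scales
#'
#' Tau-b (tie-corrected) by default, so tied enrichment values (e.g. exact
#' zeros) are handled; without ties tau-a and tau-b coincide.
#'
#' @param x,y Numeric vectors of equal length (>= 2), aligned elementwise
#'   (for scales: by amino acid).
#' @param variant `"b"` (tie-corrected, default) or `"a"` (plain
#'   concordant-discordant over all pairs).
#' @return Correlation in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y, variant = c("b", "a")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop_("x and y must have equal length")
  if (length(x) < 2L) stop_("need at least 2 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("kendall_tau undefined for an all-constant vector")
  if (variant == "b") return(unname(stats::cor(x, y, method = "kendall")))
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    dx <- sign(x[(i + 1L):n] - x[i])
    dy <- sign(y[(i + 1L):n] - y[i])
    s <- s + sum(dx * dy)
  }
  s / (n * (n - 1L) / 2)
}

#' Pairwise Kendall correlation matrix of propensity scales
#'
#' @param scales List of [propensity_scale] objects (>= 2), complete over the
#'   20 amino acids.
#' @param variant Passed to [kendall_tau()].
#' @return An object of class `scale_matrix`: list with `names` and `kcc`, a
#'   symmetric matrix with unit diagonal.
#' @export
scale_matrix <- function(scales, variant = "b") {
  if (!is.list(scales) || length(scales) < 2L)
    stop_("need at least two scales")
  if (!all(vapply(scales, inherits, logical(1), "propensity_scale")))
    stop_("all elements must be propensity_scale objects")
  nm <- vapply(scales, `[[`, character(1), "name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  k <- length(scales)
  m <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    tau <- kendall_tau(scales[[i]]$values[AA20], scales[[j]]$values[AA20],
                       variant = variant)
    m[i, j] <- m[j, i] <- tau
  }
  dimnames(m) <- list(nm, nm)
  structure(list(names = nm, kcc = m), class = "scale_matrix")
}

#' @export
print.scale_matrix <- function(x, ...) {
  cat("<scale_matrix> Kendall correlations\n")
  print(round(x$kcc, 3))
  invisible(x)
}

#' Correlation between predictor accuracy and scale agreement
#'
#' Pearson correlation between per-predictor accuracy values (e.g. AUC) and
#' per-predictor agreement of their putative-disorder composition bias with
#' the native-disorder scale (e.g. Kendall correlation).
#'
#' @param predictor_aucs,predictor_kccs Named numeric vectors over the same
#'   set of at least 3 predictors.
#' @return Pearson correlation coefficient.
#' @export
bias_performance_correlation <- function(predictor_aucs, predictor_kccs) {
  if (is.null(names(predictor_aucs)) || is.null(names(predictor_kccs)) ||
      !setequal(names(predictor_aucs), names(predictor_kccs)))
    stop_("the two vectors must be named over the same predictors")
  if (length(predictor_aucs) < 3L) stop_("need at least 3 predictors")
  x <- predictor_aucs[sort(names(predictor_aucs))]
  y <- predictor_kccs[names(x)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_("zero variance: Pearson correlation undefined")
  unname(stats::cor(x, y))
}
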