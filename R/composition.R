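# Amino-acid compositional enrichment of a residue sample against a
# background pool, with per-AA permutation significance.

# Logical mask of selected positions for one protein. `categories` is the
# categorize_idrs() table for the whole set (may be NULL for track-level
# selectors).
selector_mask <- function(p, what, categories = NULL) {
  n <- nchar(p$sequence)
  mask <- rep(FALSE, n)
  if (is.function(what)) {
    m <- what(p)
    if (!is.logical(m) || length(m) != n)
      stop_("selector function must return a logical mask of sequence length")
    return(m & !is.na(m))
  }
  switch(what,
    disorder = !is.na(p$disorder) & p$disorder == 1L,
    order = ,
    nondisordered = !is.na(p$disorder) & p$disorder == 0L,
    binding = !is.na(p$binding) & p$binding == 1L,
    fully_disordered_idr = ,
    short_idr = ,
    long_idr = ,
    binding_idr = {
      col <- sub("_idr$", "", what)
      if (col == "fully_disordered") col <- "fully_disordered"
      reg <- categories[categories$protein_id == p$id &
                          categories[[col]], , drop = FALSE]
      for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- TRUE
      mask
    },
    stop_("unknown residue selector '%s'", what)
  )
}

#' Count amino acids over selected residues
#'
#' Builds a pool of amino-acid counts over the residues a selector picks.
#' Non-standard letters (X, U, B, Z, ...) are excluded from the counts.
#'
#' @param proteins Named list of [annotated_protein].
#' @param what Either a keyword — `"disorder"`, `"order"`/`"nondisordered"`,
#'   `"binding"`, `"fully_disordered_idr"`, `"short_idr"`, `"long_idr"`,
#'   `"binding_idr"` — or a function `protein -> logical mask`.
#' @param categories Optional [categorize_idrs()] table; computed on demand
#'   for the category selectors.
#' @return Named integer vector of counts over [AA20]
#'   (class `residue_pool`, attribute `n_selected` = residues selected before
#'   dropping non-standard letters).
#' @export
residue_pool <- function(proteins, what, categories = NULL) {
  assert_protein_list(proteins)
  needs_cat <- is.character(what) &&
    what %in% c("fully_disordered_idr", "short_idr", "long_idr", "binding_idr")
  if (needs_cat && is.null(categories)) categories <- categorize_idrs(proteins)
  counts <- stats::setNames(integer(length(AA20)), AA20)
  n_sel <- 0L
  for (p in proteins) {
    mask <- selector_mask(p, what, categories)
    n_sel <- n_sel + sum(mask)
    if (!any(mask)) next
    aa <- strsplit(p$sequence, "")[[1]][mask]
    aa <- aa[aa %in% AA20]
    if (length(aa)) {
      tb <- table(factor(aa, levels = AA20))
      counts <- counts + as.integer(tb)
    }
  }
  structure(counts, n_selected = n_sel, class = c("residue_pool", "integer"))
}

#' Build disjoint sample and background residue pools
#'
#' @inheritParams residue_pool
#' @param sample,background Selectors (see [residue_pool()]). The two
#'   selections must not overlap and must both be non-empty.
#' @return List with elements `sample` and `background`, each a
#'   [residue_pool()].
#' @export
build_pools <- function(proteins, sample, background = "nondisordered",
                        categories = NULL) {
  assert_protein_list(proteins)
  cat_sel <- c("fully_disordered_idr", "short_idr", "long_idr", "binding_idr")
  needs_cat <- any(vapply(list(sample, background),
                          function(w) is.character(w) && w %in% cat_sel,
                          logical(1)))
  if (needs_cat && is.null(categories)) categories <- categorize_idrs(proteins)
  for (p in proteins) {
    ms <- selector_mask(p, sample, categories)
    mb <- selector_mask(p, background, categories)
    if (any(ms & mb))
      stop_("sample and background selections overlap in protein '%s'", p$id)
  }
  s <- residue_pool(proteins, sample, categories)
  b <- residue_pool(proteins, background, categories)
  if (sum(s) == 0L) stop_("sample selector picked no standard residues")
  if (sum(b) == 0L) stop_("background selector picked no standard residues")
  list(sample = s, background = b)
}

#' Relative compositional enrichment
#'
#' For each amino acid, `(f_sample - f_background) / f_background`, where `f`
#' are within-pool frequencies. Bounded below by -1; 0 when the frequencies
#' agree; undefined (error) when the background frequency is 0.
#'
#' @param sample,background Count vectors over [AA20] (e.g. from
#'   [residue_pool()]).
#' @param aa Optional single amino acid; when given, a scalar is returned.
#' @return Named numeric vector over [AA20], or a scalar when `aa` is given.
#' @export
enrichment <- function(sample, background, aa = NULL) {
  fs <- sample / sum(sample)
  fb <- background / sum(background)
  if (!is.null(aa)) {
    aa <- toupper(aa)
    if (!aa %in% AA20) stop_("unknown amino acid '%s'", aa)
    if (fb[[aa]] == 0) stop_("background frequency of '%s' is 0: enrichment undefined", aa)
    return(unname((fs[[aa]] - fb[[aa]]) / fb[[aa]]))
  }
  if (any(fb == 0))
    stop_("background frequency of '%s' is 0: enrichment undefined",
          AA20[which(fb == 0)[1]])
  stats::setNames((fs - fb) / fb, AA20)
}

#' Compositional-bias scale with permutation significance
#'
#' Computes the per-amino-acid enrichment of a residue sample relative to a
#' background and attaches a two-sided permutation p-value per amino acid:
#' sample and background residues are pooled and repeatedly re-split into
#' groups of the original sizes (a multivariate hypergeometric draw); the
#' p-value is the smoothed proportion of permutations whose absolute
#' frequency difference reaches the observed one,
#' `(1 + hits) / (n_resamples + 1)`. Calls are `enriched` / `depleted` when
#' `p < alpha` with positive / negative enrichment, `neutral` otherwise. No
#' multiple-testing correction is applied (one test per amino acid at
#' `alpha`).
#'
#' @param sample,background Count vectors over [AA20].
#' @param n_resamples Number of permutations (default 10000, minimum 100).
#' @param alpha Per-amino-acid significance level (default 0.05).
#' @param seed Optional seed; the result is reproducible given the seed.
#' @param name Scale name.
#' @return A `composition_scale` (subclass of [propensity_scale]): `values`
#'   are enrichments; additional fields `p_value`, `freq_sample`,
#'   `freq_background` and `meta` (sizes, settings, seed).
#' @export
compute_scale <- function(sample, background, n_resamples = 10000L,
                          alpha = 0.05, seed = NULL, name = "sample") {
  if (n_resamples < 100L) stop_("n_resamples must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop_("alpha must be in (0, 1)")
  sample <- as.integer(sample[AA20])
  background <- as.integer(background[AA20])
  ns <- sum(sample); nb <- sum(background)
  if (ns == 0L || nb == 0L) stop_("empty sample or background pool")
  fs <- sample / ns; fb <- background / nb
  if (any(fb == 0))
    stop_("background frequency of '%s' is 0: enrichment undefined",
          AA20[which(fb == 0)[1]])
  obs <- fs - fb
  enr <- obs / fb
  pooled <- sample + background
  p_value <- with_seed(seed, {
    # sequential multivariate hypergeometric split of the pooled counts
    remaining_draw <- rep(ns, n_resamples)
    remaining_total <- sum(pooled)
    pv <- numeric(20L)
    perm_counts <- matrix(0L, nrow = n_resamples, ncol = 20L)
    for (a in seq_len(20L)) {
      m <- pooled[a]
      k <- if (a < 20L)
        stats::rhyper(n_resamples, m, remaining_total - m, remaining_draw)
      else remaining_draw
      perm_counts[, a] <- k
      remaining_draw <- remaining_draw - k
      remaining_total <- remaining_total - m
    }
    for (a in seq_len(20L)) {
      d <- perm_counts[, a] / ns - (pooled[a] - perm_counts[, a]) / nb
      pv[a] <- (1 + sum(abs(d) >= abs(obs[a]) - 1e-12)) / (n_resamples + 1)
    }
    pv
  })
  names(p_value) <- AA20
  call <- ifelse(p_value >= alpha, "neutral",
                 ifelse(enr > 0, "enriched", "depleted"))
  call[p_value < alpha & enr == 0] <- "neutral"
  names(call) <- AA20
  out <- propensity_scale(name, stats::setNames(enr, AA20), call)
  out$p_value <- p_value
  out$freq_sample <- stats::setNames(fs, AA20)
  out$freq_background <- stats::setNames(fb, AA20)
  out$meta <- list(n_sample = ns, n_background = nb,
                   n_resamples = as.integer(n_resamples), alpha = alpha,
                   seed = seed)
  class(out) <- c("composition_scale", class(out))
  out
}

#' @export
print.composition_scale <- function(x, ...) {
  cat(sprintf("<composition_scale> %s (n_sample=%d, n_background=%d)\n",
              x$name, x$meta$n_sample, x$meta$n_background))
  cat(sprintf("  enriched: %s\n",
              paste(AA20[x$significance == "enriched"], collapse = " ")))
  cat(sprintf("  depleted: %s\n",
              paste(AA20[x$significance == "depleted"], collapse = " ")))
  invisible(x)
}
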