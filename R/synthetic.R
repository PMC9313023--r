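# Synthetic CAID-like datasets: annotated proteins with class-controlled
# disorder architecture, state-specific amino-acid compositions with
# injectable enrichments, and predictor tracks with per-class target AUC.

# Average amino-acid frequencies of well-folded sequence (UniProt-like
# background), used for ordered residues.
ORDER_COMPOSITION <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f <- f[AA20]
  f / sum(f)
})

# Disordered-state composition: the ordered background reweighted toward
# polar/charged residues and away from bulky hydrophobics, mirroring the
# well-known disorder bias (P, E, S, K, Q, G, D up; W, C, F, I, Y, L, V down).
DISORDER_COMPOSITION <- local({
  mult <- c(A = 1.1, C = 0.4, D = 1.2, E = 1.5, F = 0.5, G = 1.2,
            H = 0.8, I = 0.5, K = 1.4, L = 0.6, M = 0.7, N = 1.0,
            P = 1.8, Q = 1.3, R = 1.0, S = 1.4, T = 1.1, V = 0.7,
            W = 0.4, Y = 0.5)
  f <- ORDER_COMPOSITION * mult[AA20]
  f / sum(f)
})

# Apply multiplicative per-AA enrichment factors to a composition and
# renormalise.
apply_enrichment <- function(comp, factors) {
  if (is.null(factors) || !length(factors)) return(comp)
  bad <- setdiff(names(factors), AA20)
  if (length(bad)) stop_("unknown amino acid(s) in enrichment: %s",
                         paste(bad, collapse = ","))
  comp[names(factors)] <- comp[names(factors)] * unlist(factors)
  comp / sum(comp)
}

# Per-class architecture defaults: protein length, disorder content / IDR
# sizes, binding placement. All satisfy the class-definition inequalities.
default_class_params <- function() {
  list(
    fully_disordered = list(len = c(120L, 250L), content = c(0.85, 0.95),
                            binding_prob = 0.3, binding_len = c(10L, 30L)),
    low_short = list(len = c(150L, 300L), n_idr = c(1L, 2L),
                     idr_len = c(10L, 14L)),
    low_binding_long = list(idr_len = c(20L, 60L), len_mult = c(4, 8)),
    low_nonbinding_long = list(idr_len = c(20L, 60L), len_mult = c(4, 8)),
    high_binding = list(len = c(120L, 250L), content = c(0.4, 0.7),
                        n_idr = c(1L, 2L), binding_len_min = 10L),
    high_nonbinding = list(len = c(120L, 250L), content = c(0.4, 0.7),
                           n_idr = c(1L, 2L))
  )
}

#' Configuration for a synthetic CAID-like dataset
#'
#' @param n_per_class Named integer vector: number of proteins per disorder
#'   class (names from [IDP_CLASSES] excluding `unassigned`).
#' @param order_composition,disorder_composition Frequency vectors over
#'   [AA20] summing to 1 (within 1e-9) used for ordered and disordered
#'   residues.
#' @param enrichment Optional named list of multiplicative per-amino-acid
#'   factors applied to the disorder composition everywhere (renormalised).
#' @param class_enrichment Optional named list (per class) of such factor
#'   lists, applied on top of `enrichment` for that class's disordered
#'   residues.
#' @param class_params Optional per-class architecture overrides merged over
#'   the built-in defaults (protein length ranges, IDR counts and lengths,
#'   binding placement).
#' @param predictors List of predictor profiles, each
#'   `list(name = , class_auc = )` with `class_auc` a named vector of target
#'   AUCs in `[0.5, 1]` over the classes being generated.
#' @param seed Seed used by [generate_reference()] / [generate_dataset()].
#' @return An object of class `synthetic_config` (validated).
#' @export
synthetic_config <- function(n_per_class,
                             order_composition = ORDER_COMPOSITION,
                             disorder_composition = DISORDER_COMPOSITION,
                             enrichment = NULL, class_enrichment = NULL,
                             class_params = NULL, predictors = list(),
                             seed = 1L) {
  valid <- setdiff(IDP_CLASSES, "unassigned")
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% valid))
    stop_("n_per_class must be named by disorder classes (%s)",
          paste(valid, collapse = ", "))
  n_per_class <- n_per_class[n_per_class > 0]
  if (!length(n_per_class)) stop_("n_per_class requests no proteins")
  for (comp in list(order_composition, disorder_composition)) {
    if (!setequal(names(comp), AA20)) stop_("composition must cover the 20 amino acids")
    if (abs(sum(comp) - 1) > 1e-9) stop_("composition must sum to 1 (within 1e-9)")
    if (any(comp < 0)) stop_("composition frequencies must be non-negative")
  }
  if (!is.null(class_enrichment)) {
    bad <- setdiff(names(class_enrichment), valid)
    if (length(bad)) stop_("class_enrichment for unknown class: %s",
                           paste(bad, collapse = ", "))
  }
  params <- default_class_params()
  if (!is.null(class_params)) {
    bad <- setdiff(names(class_params), valid)
    if (length(bad)) stop_("class_params for unknown class: %s",
                           paste(bad, collapse = ", "))
    for (cls in names(class_params))
      params[[cls]] <- utils::modifyList(params[[cls]], class_params[[cls]])
  }
  for (pr in predictors) {
    if (is.null(pr$name) || is.null(pr$class_auc))
      stop_("each predictor profile needs 'name' and 'class_auc'")
    bad <- setdiff(names(pr$class_auc), IDP_CLASSES)
    if (length(bad)) stop_("predictor '%s': unknown class in profile: %s",
                           pr$name, paste(bad, collapse = ", "))
    if (any(pr$class_auc < 0.5 | pr$class_auc > 1))
      stop_("predictor '%s': target AUCs must be in [0.5, 1]", pr$name)
    miss <- setdiff(names(n_per_class), names(pr$class_auc))
    if (length(miss)) stop_("predictor '%s': no target AUC for class %s",
                            pr$name, paste(miss, collapse = ", "))
  }
  # feasibility of the architecture against the class rules
  p <- params$fully_disordered
  if (p$content[1] < 0.8) stop_("fully_disordered content range must start >= 0.8")
  p <- params$low_short
  if (p$idr_len[1] < 10L || p$idr_len[2] > 14L)
    stop_("low_short IDR lengths must lie in [10, 14]")
  if (max(p$n_idr) * p$idr_len[2] / p$len[1] > 0.3)
    stop_("low_short architecture can exceed disorder content 0.3")
  for (cls in c("low_binding_long", "low_nonbinding_long")) {
    p <- params[[cls]]
    if (p$idr_len[1] <= 15L) stop_("%s IDRs must be > 15 residues", cls)
    if (1 / p$len_mult[1] > 0.3)
      stop_("%s: len_mult too small for disorder content <= 0.3", cls)
  }
  for (cls in c("high_binding", "high_nonbinding")) {
    p <- params[[cls]]
    if (p$content[1] <= 0.3 || p$content[2] >= 0.8)
      stop_("%s content range must lie strictly inside (0.3, 0.8)", cls)
  }
  structure(list(n_per_class = n_per_class,
                 order_composition = order_composition[AA20],
                 disorder_composition = disorder_composition[AA20],
                 enrichment = enrichment, class_enrichment = class_enrichment,
                 class_params = params, predictors = predictors,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Random integer in [a, b].
rint <- function(rng) if (rng[1] >= rng[2]) as.integer(rng[1]) else
  sample(rng[1]:rng[2], 1L)

# Place k region lengths inside length L with >= 1 separator between
# consecutive regions; returns data.frame(start, end).
place_regions <- function(L, lens) {
  k <- length(lens)
  slack <- L - sum(lens) - (k - 1L)
  if (slack < 0L) stop_("regions do not fit in protein of length %d", L)
  gaps <- as.integer(stats::rmultinom(1, slack, rep(1, k + 1L)))
  starts <- integer(k)
  pos <- 1L + gaps[1]
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + lens[i] + 1L + gaps[i + 1L]
  }
  data.frame(start = starts, end = starts + lens - 1L)
}

# Architecture for one protein of the given class: length, disorder regions,
# binding regions.
draw_architecture <- function(cls, params) {
  p <- params[[cls]]
  binding <- data.frame(start = integer(), end = integer())
  if (cls == "fully_disordered") {
    L <- rint(p$len)
    u <- stats::runif(1, p$content[1], p$content[2])
    d <- min(L, as.integer(ceiling(u * L)))
    reg <- place_regions(L, d)
    if (stats::runif(1) < p$binding_prob) {
      bl <- min(rint(p$binding_len), d)
      bs <- reg$start + rint(c(0L, d - bl))
      binding <- data.frame(start = bs, end = bs + bl - 1L)
    }
  } else if (cls == "low_short") {
    L <- rint(p$len)
    k <- rint(p$n_idr)
    lens <- vapply(seq_len(k), function(i) rint(p$idr_len), integer(1))
    reg <- place_regions(L, lens)
  } else if (cls %in% c("low_binding_long", "low_nonbinding_long")) {
    il <- rint(p$idr_len)
    L <- as.integer(round(il * stats::runif(1, p$len_mult[1], p$len_mult[2])))
    reg <- place_regions(L, il)
    if (cls == "low_binding_long") binding <- reg
  } else { # high_binding / high_nonbinding
    L <- rint(p$len)
    u <- stats::runif(1, p$content[1], p$content[2])
    d <- as.integer(round(u * L))
    k <- min(rint(p$n_idr), d %/% 10L)
    extra <- as.integer(stats::rmultinom(1, d - 10L * k, rep(1, k)))
    lens <- 10L + extra
    reg <- place_regions(L, lens)
    if (cls == "high_binding") {
      i <- which.max(lens)
      bl <- rint(c(min(p$binding_len_min, lens[i]), lens[i]))
      bs <- reg$start[i] + rint(c(0L, lens[i] - bl))
      binding <- data.frame(start = bs, end = bs + bl - 1L)
    }
  }
  list(L = L, disorder = reg, binding = binding)
}

#' Generate a synthetic annotated reference set
#'
#' For each requested class, proteins whose disorder architecture satisfies
#' that class's rule by construction; residues are drawn i.i.d. from the
#' state-appropriate composition (the disorder composition optionally
#' reweighted by global and per-class enrichment factors). The derived class
#' of every generated protein is re-checked against the intended one.
#'
#' @param config A [synthetic_config()].
#' @return List with `proteins` (named list of [annotated_protein]),
#'   `classes` (ground-truth data frame `protein_id`, `class`) and `regions`
#'   (ground-truth disorder/binding region table).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    proteins <- list()
    truth <- list()
    regions <- list()
    idx <- 0L
    for (cls in names(config$n_per_class)) {
      dis_comp <- apply_enrichment(config$disorder_composition, config$enrichment)
      dis_comp <- apply_enrichment(dis_comp, config$class_enrichment[[cls]])
      for (i in seq_len(config$n_per_class[[cls]])) {
        idx <- idx + 1L
        id <- sprintf("SYN%04d", idx)
        arch <- draw_architecture(cls, config$class_params)
        dis <- rep(0L, arch$L); bnd <- rep(0L, arch$L)
        for (r in seq_len(nrow(arch$disorder)))
          dis[arch$disorder$start[r]:arch$disorder$end[r]] <- 1L
        for (r in seq_len(nrow(arch$binding)))
          bnd[arch$binding$start[r]:arch$binding$end[r]] <- 1L
        aa <- character(arch$L)
        n_d <- sum(dis); n_o <- arch$L - n_d
        if (n_d) aa[dis == 1L] <- sample(AA20, n_d, replace = TRUE, prob = dis_comp)
        if (n_o) aa[dis == 0L] <- sample(AA20, n_o, replace = TRUE,
                                         prob = config$order_composition)
        proteins[[id]] <- annotated_protein(id, paste(aa, collapse = ""),
                                            disorder = dis, binding = bnd)
        truth[[id]] <- cls
        if (nrow(arch$disorder))
          regions[[length(regions) + 1L]] <-
            data.frame(protein_id = id, start = arch$disorder$start,
                       end = arch$disorder$end, kind = "disorder",
                       stringsAsFactors = FALSE)
        if (nrow(arch$binding))
          regions[[length(regions) + 1L]] <-
            data.frame(protein_id = id, start = arch$binding$start,
                       end = arch$binding$end, kind = "binding",
                       stringsAsFactors = FALSE)
      }
    }
    classes <- data.frame(protein_id = names(truth),
                          class = unname(unlist(truth)),
                          stringsAsFactors = FALSE)
    derived <- classify_idps(proteins)
    bad <- classes$protein_id[derived$class[match(classes$protein_id,
                                                  derived$protein_id)] != classes$class]
    if (length(bad))
      stop_("internal error: generated protein(s) do not re-derive their class: %s",
            paste(utils::head(bad, 3), collapse = ", "))
    list(proteins = proteins, classes = classes,
         regions = if (length(regions))
           do.call(rbind, c(regions, list(make.row.names = FALSE))) else NULL)
  })
}

#' Generate a predictor score track with per-class target AUC
#'
#' Scores follow the binormal model: negative residues draw
#' `N(0,1)`, positives `N(delta, 1)` with `delta = sqrt(2) * qnorm(AUC)`, so
#' the expected pooled AUC within a class equals the target; raw scores are
#' mapped to `[0, 1]` by a fixed logistic squashing (AUC-invariant) and calls
#' threshold the raw scores at the class midpoint `delta / 2`. A target of 1
#' is handled as the separation limit (all positives above all negatives).
#' Unannotated residues score as negatives.
#'
#' @param proteins Named list of [annotated_protein].
#' @param classes Ground-truth or derived class table (`protein_id`,
#'   `class`).
#' @param name Predictor name.
#' @param class_auc Named vector of target AUCs in `[0.5, 1]` covering every
#'   class present in `classes`.
#' @param seed Optional seed.
#' @return A [prediction_track] with scores and calls.
#' @export
generate_predictions <- function(proteins, classes, name, class_auc,
                                 seed = NULL) {
  assert_protein_list(proteins)
  bad <- setdiff(names(class_auc), IDP_CLASSES)
  if (length(bad)) stop_("unknown class in profile: %s", paste(bad, collapse = ", "))
  if (any(class_auc < 0.5 | class_auc > 1)) stop_("target AUCs must be in [0.5, 1]")
  cls_of <- stats::setNames(classes$class, classes$protein_id)
  present <- unique(cls_of[names(proteins)])
  miss <- setdiff(present, names(class_auc))
  if (length(miss)) stop_("no target AUC for class: %s", paste(miss, collapse = ", "))
  with_seed(seed, {
    scores <- calls <- list()
    for (id in names(proteins)) {
      p <- proteins[[id]]
      n <- nchar(p$sequence)
      pos <- !is.na(p$disorder) & p$disorder == 1L
      target <- class_auc[[cls_of[[id]]]]
      z <- stats::rnorm(n)
      if (target >= 1) {
        s <- stats::plogis(z) / 2
        s[pos] <- 0.5 + stats::plogis(z[pos]) / 2
        cl <- as.integer(s > 0.5)
      } else {
        delta <- sqrt(2) * stats::qnorm(target)
        z[pos] <- z[pos] + delta
        s <- stats::plogis(z)
        cl <- as.integer(z >= delta / 2)
      }
      scores[[id]] <- s
      calls[[id]] <- cl
    }
    prediction_track(name, scores, calls)
  })
}

#' Built-in synthetic presets
#'
#' \describe{
#'   \item{`null`}{Disorder and order residues share one composition; one
#'     mediocre predictor. Used for significance-calibration checks.}
#'   \item{`biased_scales`}{Three distinct injected bias profiles — one for
#'     fully disordered proteins, one for short-IDR proteins, one shared by
#'     the long/binding classes — mirroring the three bias types seen in
#'     native disorder.}
#'   \item{`class_specialists`}{Six predictors, each with target AUC 0.95 on
#'     its own class and 0.55 elsewhere; the meta-predictor's natural
#'     habitat.}
#'   \item{`caid_like`}{A ~250-protein class mixture whose IDR length
#'     statistics loosely match the CAID reference set (overall median IDR
#'     length near 34, short-IDR median near 12).}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("null", "biased_scales",
                                      "class_specialists", "caid_like"),
                             seed = 1L) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop_("unknown preset '%s'; available: null, biased_scales, class_specialists, caid_like",
                           name[1]))
  switch(name,
    null = synthetic_config(
      n_per_class = c(high_binding = 20L, high_nonbinding = 20L),
      disorder_composition = ORDER_COMPOSITION,
      class_params = list(
        high_binding = list(len = c(200L, 300L), content = c(0.4, 0.6)),
        high_nonbinding = list(len = c(200L, 300L), content = c(0.4, 0.6))),
      predictors = list(list(name = "mediocre",
                             class_auc = c(high_binding = 0.7,
                                           high_nonbinding = 0.7))),
      seed = seed),
    biased_scales = synthetic_config(
      n_per_class = c(fully_disordered = 15L, low_short = 25L,
                      low_binding_long = 15L, low_nonbinding_long = 15L,
                      high_binding = 15L, high_nonbinding = 15L),
      class_enrichment = list(
        fully_disordered = list(G = 1.6, S = 1.4, Q = 1.3, W = 0.5),
        low_short = list(D = 1.6, E = 1.4, P = 0.6),
        low_binding_long = list(P = 1.8, K = 1.4, F = 0.5),
        low_nonbinding_long = list(P = 1.8, K = 1.4, F = 0.5),
        high_binding = list(P = 1.8, K = 1.4, F = 0.5)),
      seed = seed),
    class_specialists = local({
      cls <- setdiff(IDP_CLASSES, "unassigned")
      preds <- lapply(cls, function(own) {
        auc <- stats::setNames(rep(0.55, length(cls)), cls)
        auc[own] <- 0.95
        list(name = paste0("spec_", own), class_auc = auc)
      })
      synthetic_config(
        n_per_class = stats::setNames(rep(20L, length(cls)), cls),
        predictors = preds, seed = seed)
    }),
    caid_like = synthetic_config(
      n_per_class = c(fully_disordered = 20L, low_short = 45L,
                      low_binding_long = 25L, low_nonbinding_long = 25L,
                      high_binding = 70L, high_nonbinding = 65L),
      class_params = list(
        high_binding = list(len = c(120L, 260L), content = c(0.35, 0.7),
                            n_idr = c(1L, 3L)),
        high_nonbinding = list(len = c(120L, 260L), content = c(0.35, 0.7),
                               n_idr = c(1L, 3L))),
      predictors = list(
        list(name = "strong", class_auc = stats::setNames(
          rep(0.82, 6), setdiff(IDP_CLASSES, "unassigned"))),
        list(name = "weak", class_auc = stats::setNames(
          rep(0.7, 6), setdiff(IDP_CLASSES, "unassigned")))),
      seed = seed)
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_reference()] and [generate_predictions()] for every
#' predictor profile in the config, deriving per-predictor seeds from the
#' config seed.
#'
#' @param config A [synthetic_config()] or a preset name accepted by
#'   [synthetic_preset()].
#' @param seed Optional override of the config seed.
#' @return List with `proteins`, `classes`, `regions` and `tracks` (named
#'   list of [prediction_track]).
#' @export
generate_dataset <- function(config, seed = NULL) {
  if (is.character(config)) config <- synthetic_preset(config, seed = seed %||% 1L)
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  ref <- generate_reference(config)
  tracks <- list()
  for (i in seq_along(config$predictors)) {
    pr <- config$predictors[[i]]
    tracks[[pr$name]] <- generate_predictions(
      ref$proteins, ref$classes, pr$name, pr$class_auc,
      seed = derive_seed(config$seed, i))
  }
  c(ref, list(tracks = tracks))
}
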