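# End-to-end orchestration: parse or simulate -> regions/classes -> scales ->
# Kendall matrix -> per-class evaluation -> bootstrap comparisons -> meta.

#' Build a validated pipeline configuration
#'
#' Either real input files (`reference`, optionally `binding` and
#' `predictions`) or a synthetic `preset` / [synthetic_config()] must be
#' supplied, not neither.
#'
#' @param reference,binding Paths to CAID-style reference files.
#' @param predictions Character vector of prediction-file paths.
#' @param preset A [synthetic_preset()] name or a [synthetic_config()].
#' @param external_scale Optional path to a propensity-scale TSV that joins
#'   the Kendall comparison (e.g. a published disorder-propensity scale).
#' @param routing Optional [meta_routing()] vector; when `NULL` and at least
#'   two predictors are available, the best predictor per class (by AUC) is
#'   routed automatically.
#' @param n_resamples,alpha Settings for [compute_scale()].
#' @param n_iter,fraction Settings for [bootstrap_compare()].
#' @param output_dir Directory the report bundle is written to.
#' @param seed Run seed; per-stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(reference = NULL, binding = NULL, predictions = NULL,
                       preset = NULL, external_scale = NULL, routing = NULL,
                       n_resamples = 2000L, alpha = 0.05, n_iter = 100L,
                       fraction = 0.5, output_dir = tempfile("idrbias_run_"),
                       seed = 1L) {
  if (is.null(reference) && is.null(preset))
    stop_("either a reference file or a synthetic preset must be supplied")
  if (!is.null(reference) && !is.null(preset))
    stop_("supply real inputs or a synthetic preset, not both")
  structure(list(reference = reference, binding = binding,
                 predictions = predictions, preset = preset,
                 external_scale = external_scale, routing = routing,
                 n_resamples = as.integer(n_resamples), alpha = alpha,
                 n_iter = as.integer(n_iter), fraction = fraction,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete analysis pipeline
#'
#' Stages: load or generate the annotated proteins and predictor tracks;
#' summarise IDR categories; compute the overall and per-category
#' composition scales against the non-disordered background; compute the
#' Kendall correlation matrix of all scales (plus predictor-bias scales and
#' an optional external scale); evaluate every predictor overall and per
#' disorder class; assemble and evaluate the class-routed meta-predictor;
#' compare it to each component with the bootstrap protocol. Every number in
#' the bundle comes from the corresponding module function.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results (`summary`, `scales`,
#'   `kcc`, `per_class`, `meta_eval`, `bootstrap`, `manifest`). The report
#'   bundle (`summary.tsv`, `scales/*.tsv`, `kcc.tsv`,
#'   `per_class_metrics.tsv`, `bootstrap.tsv`, `meta_eval.tsv`,
#'   `manifest.json`) is written to `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$output_dir, "scales"), showWarnings = FALSE)

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$preset)) {
    ds <- generate_dataset(config$preset, seed = config$seed)
    proteins <- ds$proteins; tracks <- ds$tracks
  } else {
    proteins <- read_reference(config$reference)
    if (!is.null(config$binding))
      proteins <- merge_binding(proteins,
                                read_reference(config$binding, track = "binding"))
    else
      for (id in names(proteins))
        proteins[[id]]$binding <- rep(0L, nchar(proteins[[id]]$sequence))
    tracks <- list()
    for (pf in config$predictions %||% character()) {
      tr <- read_predictions(pf, reference = proteins)
      tracks[[tr$name]] <- tr
    }
  }
  classes <- classify_idps(proteins)
  categories <- categorize_idrs(proteins)

  # --- stage: summary and composition scales -------------------------------
  summary_tbl <- region_summary(proteins)
  write_tsv(summary_tbl, file.path(config$output_dir, "summary.tsv"))

  scale_specs <- c(overall = "disorder", fully_disordered = "fully_disordered_idr",
                   short = "short_idr", long = "long_idr", binding = "binding_idr")
  scales <- list()
  for (i in seq_along(scale_specs)) {
    nm <- names(scale_specs)[i]
    pools <- tryCatch(build_pools(proteins, scale_specs[[i]], "nondisordered",
                                  categories = categories),
                      error = function(e) NULL)
    if (is.null(pools)) next
    scales[[nm]] <- compute_scale(pools$sample, pools$background,
                                  n_resamples = config$n_resamples,
                                  alpha = config$alpha,
                                  seed = derive_seed(config$seed, 10L + i),
                                  name = nm)
    write_scale(scales[[nm]], file.path(config$output_dir, "scales",
                                        paste0(nm, ".tsv")))
  }

  # predictor-bias scales: putative disordered vs putative ordered residues,
  # using each predictor's own binary calls
  for (tr in tracks) {
    if (is.null(tr$calls)) next
    sel_pos <- local({t <- tr; function(p) t$calls[[p$id]] == 1L})
    sel_neg <- local({t <- tr; function(p) t$calls[[p$id]] == 0L})
    pools <- tryCatch(build_pools(proteins, sel_pos, sel_neg),
                      error = function(e) NULL)
    if (is.null(pools)) next
    nm <- paste0("pred_", tr$name)
    scales[[nm]] <- compute_scale(pools$sample, pools$background,
                                  n_resamples = config$n_resamples,
                                  alpha = config$alpha,
                                  seed = derive_seed(config$seed, 30L + length(scales)),
                                  name = nm)
    write_scale(scales[[nm]], file.path(config$output_dir, "scales",
                                        paste0(nm, ".tsv")))
  }
  if (!is.null(config$external_scale))
    scales[["external"]] <- read_scale(config$external_scale, name = "external")

  kcc <- NULL
  if (length(scales) >= 2L) {
    kcc <- scale_matrix(unname(scales))
    long <- data.frame(name_a = rep(kcc$names, each = length(kcc$names)),
                       name_b = rep(kcc$names, times = length(kcc$names)),
                       kcc = as.vector(t(kcc$kcc)), stringsAsFactors = FALSE)
    write_tsv(long, file.path(config$output_dir, "kcc.tsv"))
  }

  # --- stage: evaluation, meta, bootstrap ----------------------------------
  per_class <- meta_eval <- boot_tbl <- NULL
  if (length(tracks)) {
    per_class <- evaluate_by_class(tracks, proteins, classes)
    write_tsv(per_class, file.path(config$output_dir, "per_class_metrics.tsv"))
  }
  if (length(tracks) >= 2L) {
    routing <- config$routing %||% best_routing(per_class)
    meta <- assemble_meta(tracks, routing, classes, proteins)
    meta_eval <- rbind(evaluate(meta, proteins),
                       do.call(rbind, lapply(tracks, evaluate, proteins)))
    meta_eval <- meta_eval[order(-meta_eval$auc), ]
    rownames(meta_eval) <- NULL
    write_tsv(meta_eval, file.path(config$output_dir, "meta_eval.tsv"))
    rows <- list()
    for (i in seq_along(tracks)) {
      bc <- bootstrap_compare(meta, tracks[[i]], proteins, metric = "auc",
                              n_iter = config$n_iter,
                              fraction = config$fraction,
                              seed = derive_seed(config$seed, 60L + i))
      rows[[i]] <- data.frame(method_a = bc$method_a, method_b = bc$method_b,
                              metric = bc$metric,
                              mean_a = mean(bc$values_a),
                              mean_b = mean(bc$values_b),
                              test_used = bc$test_used, p_value = bc$p_value,
                              stringsAsFactors = FALSE)
    }
    boot_tbl <- do.call(rbind, rows)
    write_tsv(boot_tbl, file.path(config$output_dir, "bootstrap.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("idrbias")),
    seed = config$seed,
    n_resamples = config$n_resamples, alpha = config$alpha,
    n_iter = config$n_iter, fraction = config$fraction,
    preset = if (is.character(config$preset)) config$preset
             else if (!is.null(config$preset)) "custom_config" else NULL,
    inputs = list(reference = config$reference, binding = config$binding,
                  predictions = config$predictions),
    n_proteins = length(proteins), n_residues = residue_count(proteins),
    classes = as.list(table(classes$class)),
    routing = as.list(config$routing %||%
                        (if (length(tracks) >= 2L) best_routing(per_class) else NULL))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(proteins = proteins, classes = classes, tracks = tracks,
                 summary = summary_tbl, scales = scales, kcc = kcc,
                 per_class = per_class, meta_eval = meta_eval,
                 bootstrap = boot_tbl, manifest = manifest))
}

#' Route each class to its best predictor by AUC
#'
#' @param per_class An [evaluate_by_class()] table.
#' @param default Predictor used for classes with no evaluable result and for
#'   unassigned proteins; defaults to the predictor with the best overall
#'   AUC.
#' @return A [meta_routing()] vector.
#' @export
best_routing <- function(per_class, default = NULL) {
  overall <- per_class[per_class$subset == "all", ]
  if (is.null(default)) default <- overall$predictor[which.max(overall$auc)]
  r <- character()
  for (cls in setdiff(IDP_CLASSES, "unassigned")) {
    sub <- per_class[per_class$subset == cls & !is.na(per_class$auc), ]
    r[cls] <- if (nrow(sub)) sub$predictor[which.max(sub$auc)] else default
  }
  meta_routing(r, default = default)
}
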