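# Readers/writers for CAID-style reference files, per-residue prediction
# files and amino-acid propensity-scale tables, plus the basic containers.

#' Construct an annotated protein
#'
#' The per-residue containers used throughout the package. Tracks are integer
#' vectors aligned with the sequence: `1` = positive state (disordered /
#' binding), `0` = negative state, `NA` = unannotated.
#'
#' @param id Non-empty accession string.
#' @param sequence Amino-acid sequence (one-letter codes; non-standard letters
#'   such as X/U/B/Z are kept in the sequence but excluded from composition
#'   counts).
#' @param disorder Integer vector (`0`/`1`/`NA`) of the same length as
#'   `sequence`; defaults to all `NA` (unannotated).
#' @param binding Integer vector (`0`/`1`/`NA`) of the same length as
#'   `sequence`; defaults to all `0` (non-binding).
#' @return An object of class `annotated_protein`.
#' @export
annotated_protein <- function(id, sequence, disorder = NULL, binding = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_("protein id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n == 0L) stop_("protein '%s': empty sequence", id)
  disorder <- if (is.null(disorder)) rep(NA_integer_, n) else as.integer(disorder)
  binding <- if (is.null(binding)) rep(0L, n) else as.integer(binding)
  if (length(disorder) != n || length(binding) != n)
    stop_("protein '%s': track length (%d/%d) does not match sequence length %d",
          id, length(disorder), length(binding), n)
  for (tr in list(disorder, binding))
    if (!all(tr %in% c(0L, 1L, NA_integer_)))
      stop_("protein '%s': track values must be 0, 1 or NA", id)
  structure(list(id = id, sequence = sequence,
                 disorder = disorder, binding = binding),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<annotated_protein> %s: %d aa, %d disordered, %d binding\n",
              x$id, n, sum(x$disorder == 1L, na.rm = TRUE),
              sum(x$binding == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Construct a prediction track
#'
#' Per-residue scores (and optional binary calls) from one predictor over a
#' set of proteins.
#'
#' @param name Predictor name.
#' @param scores Named list of numeric vectors, one per protein id.
#' @param calls Optional named list of 0/1 integer vectors matching `scores`.
#' @return An object of class `prediction_track`.
#' @export
prediction_track <- function(name, scores, calls = NULL) {
  if (!is.character(name) || !nzchar(name)) stop_("predictor name must be non-empty")
  if (!is.list(scores) || is.null(names(scores)) || any(!nzchar(names(scores))))
    stop_("scores must be a named list of numeric vectors")
  for (id in names(scores)) {
    s <- scores[[id]]
    if (!is.numeric(s) || any(!is.finite(s)))
      stop_("predictor '%s', protein '%s': scores must be finite numerics", name, id)
  }
  if (!is.null(calls)) {
    if (!setequal(names(calls), names(scores)))
      stop_("calls and scores must cover the same protein ids")
    for (id in names(calls)) {
      cl <- as.integer(calls[[id]])
      if (length(cl) != length(scores[[id]]) || !all(cl %in% c(0L, 1L)))
        stop_("predictor '%s', protein '%s': calls must be 0/1 and aligned with scores",
              name, id)
      calls[[id]] <- cl
    }
  }
  structure(list(name = name, scores = scores, calls = calls),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  cat(sprintf("<prediction_track> %s: %d proteins, %d residues, calls: %s\n",
              x$name, length(x$scores),
              sum(lengths(x$scores)), if (is.null(x$calls)) "no" else "yes"))
  invisible(x)
}

#' Construct an amino-acid propensity scale
#'
#' @param name Scale name.
#' @param values Numeric vector with one value per standard amino acid; must be
#'   named by the 20 one-letter codes (any order; stored in [AA20] order).
#' @param significance Optional character vector (same names) with values in
#'   `"depleted"`, `"neutral"`, `"enriched"`.
#' @return An object of class `propensity_scale`.
#' @export
propensity_scale <- function(name, values, significance = NULL) {
  if (is.null(names(values)) || !setequal(names(values), AA20)) {
    missing <- setdiff(AA20, names(values))
    extra <- setdiff(names(values), AA20)
    stop_("scale '%s': values must be named by the 20 standard amino acids%s%s",
          name,
          if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")) else "",
          if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ",")) else "")
  }
  values <- as.numeric(values[AA20])
  names(values) <- AA20
  if (any(!is.finite(values))) stop_("scale '%s': non-finite values", name)
  if (!is.null(significance)) {
    if (!setequal(names(significance), AA20))
      stop_("scale '%s': significance must cover all 20 amino acids", name)
    significance <- as.character(significance[AA20])
    names(significance) <- AA20
    if (!all(significance %in% c("depleted", "neutral", "enriched")))
      stop_("scale '%s': significance must be depleted/neutral/enriched", name)
  }
  structure(list(name = name, values = values, significance = significance),
            class = "propensity_scale")
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat(sprintf("<propensity_scale> %s\n", x$name))
  ord <- order(x$values, decreasing = TRUE)
  top <- paste(sprintf("%s=%.3g", AA20[ord][1:5], x$values[ord][1:5]), collapse = " ")
  cat("  top:", top, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reference files

#' Read a CAID-style per-residue reference file
#'
#' The default dialect uses three physical lines per entry: a `>`-prefixed
#' header with the accession, the amino-acid sequence, and a label string of
#' the same length over `1` (positive state), `0` (negative state) and `-`
#' (unannotated).
#'
#' @param path Path to the reference file.
#' @param track Which track the labels describe: `"disorder"` (default) or
#'   `"binding"`.
#' @param labels Named character vector giving the label alphabet; entries
#'   `pos`, `neg`, `unann`.
#' @return A named list of [annotated_protein] objects (names are accessions).
#'   When `track = "disorder"` the binding track is initialised to all
#'   unannotated (`NA`); use [merge_binding()] to fold in a binding reference.
#' @export
read_reference <- function(path, track = c("disorder", "binding"),
                           labels = c(pos = "1", neg = "0", unann = "-")) {
  track <- match.arg(track)
  if (!file.exists(path)) stop_("reference file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop_("%s: expected '>' header on first line", path)
  n_entries <- sum(hdr)
  if (length(lines) != 3L * n_entries)
    stop_("%s: expected 3 lines per entry, got %d lines for %d headers",
          path, length(lines), n_entries)
  out <- vector("list", n_entries)
  ids <- character(n_entries)
  for (i in seq_len(n_entries)) {
    j <- 3L * (i - 1L) + 1L
    if (!grepl("^>", lines[j]))
      stop_("%s: entry %d: malformed header '%s'", path, i, lines[j])
    id <- trimws(sub("^>", "", lines[j]))
    id <- strsplit(id, "[ \t]")[[1]][1]
    seqs <- trimws(lines[j + 1L])
    lab <- trimws(lines[j + 2L])
    if (nchar(seqs) != nchar(lab))
      stop_("%s: entry '%s': sequence length %d != label length %d",
            path, id, nchar(seqs), nchar(lab))
    chars <- strsplit(lab, "")[[1]]
    bad <- setdiff(unique(chars), unname(labels))
    if (length(bad))
      stop_("%s: entry '%s': unknown label character(s): %s",
            path, id, paste(bad, collapse = ""))
    tr <- rep(NA_integer_, length(chars))
    tr[chars == labels[["pos"]]] <- 1L
    tr[chars == labels[["neg"]]] <- 0L
    ids[i] <- id
    out[[i]] <- if (track == "disorder")
      annotated_protein(id, seqs, disorder = tr,
                        binding = rep(NA_integer_, length(chars)))
    else
      annotated_protein(id, seqs, disorder = rep(NA_integer_, length(chars)),
                        binding = tr)
  }
  if (anyDuplicated(ids))
    stop_("%s: duplicate protein id: %s", path, ids[duplicated(ids)][1])
  names(out) <- ids
  out
}

#' Merge a binding reference into a disorder reference
#'
#' @param proteins Named list of [annotated_protein] from the disorder
#'   reference.
#' @param binding Named list of [annotated_protein] from the binding reference
#'   (read with `track = "binding"`).
#' @param missing How to treat proteins absent from the binding reference:
#'   `"nonbinding"` (default; binding is a subset annotation) or
#'   `"unannotated"` (strict mode).
#' @return The merged protein list.
#' @export
merge_binding <- function(proteins, binding,
                          missing = c("nonbinding", "unannotated")) {
  missing <- match.arg(missing)
  assert_protein_list(proteins)
  assert_protein_list(binding)
  extra <- setdiff(names(binding), names(proteins))
  if (length(extra))
    stop_("binding reference contains unknown protein(s): %s",
          paste(utils::head(extra, 3), collapse = ", "))
  for (id in names(proteins)) {
    n <- nchar(proteins[[id]]$sequence)
    if (id %in% names(binding)) {
      b <- binding[[id]]
      if (nchar(b$sequence) != n)
        stop_("protein '%s': binding reference length %d != disorder reference length %d",
              id, nchar(b$sequence), n)
      proteins[[id]]$binding <- b$binding
    } else {
      proteins[[id]]$binding <- if (missing == "nonbinding") rep(0L, n)
                                else rep(NA_integer_, n)
    }
  }
  proteins
}

#' Write a CAID-style reference file
#'
#' Inverse of [read_reference()]; used mainly to serialise synthetic datasets.
#'
#' @inheritParams read_reference
#' @param proteins Named list of [annotated_protein].
#' @export
write_reference <- function(proteins, path, track = c("disorder", "binding"),
                            labels = c(pos = "1", neg = "0", unann = "-")) {
  track <- match.arg(track)
  assert_protein_list(proteins)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in proteins) {
    tr <- p[[track]]
    lab <- rep(labels[["unann"]], length(tr))
    lab[!is.na(tr) & tr == 1L] <- labels[["pos"]]
    lab[!is.na(tr) & tr == 0L] <- labels[["neg"]]
    writeLines(c(paste0(">", p$id), p$sequence, paste(lab, collapse = "")), con)
  }
  invisible(path)
}

#' Count residues in a protein set
#'
#' @param proteins Named list of [annotated_protein].
#' @return Total number of residues (sum of sequence lengths).
#' @export
residue_count <- function(proteins) {
  assert_protein_list(proteins)
  sum(vapply(proteins, function(p) nchar(p$sequence), numeric(1)))
}

# ---------------------------------------------------------------------------
# Prediction files

#' Read a CAID-style per-residue prediction file
#'
#' One block per protein: a `>`-prefixed header with the accession, then one
#' line per residue with whitespace/tab-separated fields
#' `index  residue  score  [call]`. Residue indices must be 1..n without gaps.
#'
#' @param path Path to the prediction file.
#' @param name Predictor name; defaults to the file name without extension.
#' @param sep Field separator regular expression (default any whitespace).
#' @param reference Optional protein list; when supplied, residue letters and
#'   per-protein lengths are validated against it.
#' @return A [prediction_track].
#' @export
read_predictions <- function(path, name = NULL, sep = "[ \t]+", reference = NULL) {
  if (!file.exists(path)) stop_("prediction file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx) || hdr_idx[1] != 1L)
    stop_("%s: expected '>' header on first line", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  scores <- list()
  calls <- list()
  has_calls <- NA
  for (b in seq_along(hdr_idx)) {
    id <- strsplit(trimws(sub("^>", "", lines[hdr_idx[b]])), "[ \t]")[[1]][1]
    if (id %in% names(scores)) stop_("%s: duplicate block for protein '%s'", path, id)
    body <- lines[seq(hdr_idx[b] + 1L, bounds[b + 1L] - 1L)]
    if (bounds[b + 1L] - 1L < hdr_idx[b] + 1L)
      stop_("%s: protein '%s': empty block", path, id)
    fields <- strsplit(trimws(body), sep)
    nf <- lengths(fields)
    if (any(nf < 3L) || length(unique(nf)) != 1L)
      stop_("%s: protein '%s': expected uniform 3- or 4-field residue lines", path, id)
    m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
    idx <- suppressWarnings(as.integer(m[, 1]))
    if (any(is.na(idx)) || !identical(idx, seq_along(idx)))
      stop_("%s: protein '%s': residue indices must be 1..n without gaps", path, id)
    sc <- suppressWarnings(as.numeric(m[, 3]))
    if (any(!is.finite(sc)))
      stop_("%s: protein '%s': unparseable score at residue %d",
            path, id, which(!is.finite(sc))[1])
    if (!is.null(reference)) {
      if (!id %in% names(reference))
        stop_("%s: protein '%s' not present in reference", path, id)
      refseq <- strsplit(reference[[id]]$sequence, "")[[1]]
      if (length(refseq) != length(sc))
        stop_("%s: protein '%s': %d residue lines for a %d-residue reference protein",
              path, id, length(sc), length(refseq))
      if (!all(m[, 2] == refseq))
        stop_("%s: protein '%s': residue letters disagree with reference", path, id)
    }
    blk_has_calls <- nf[1] >= 4L
    if (is.na(has_calls)) has_calls <- blk_has_calls
    if (blk_has_calls != has_calls)
      stop_("%s: inconsistent presence of binary calls across blocks", path)
    scores[[id]] <- sc
    if (has_calls) {
      cl <- suppressWarnings(as.integer(m[, 4]))
      if (any(is.na(cl)) || !all(cl %in% c(0L, 1L)))
        stop_("%s: protein '%s': binary calls must be 0/1", path, id)
      calls[[id]] <- cl
    }
  }
  prediction_track(name, scores, if (isTRUE(has_calls)) calls else NULL)
}

#' Write a CAID-style prediction file
#'
#' @param track A [prediction_track].
#' @param path Output path.
#' @param proteins Optional protein list supplying residue letters; `"X"` is
#'   written when absent.
#' @export
write_predictions <- function(track, path, proteins = NULL) {
  stopifnot(inherits(track, "prediction_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(track$scores)) {
    s <- track$scores[[id]]
    res <- if (!is.null(proteins) && id %in% names(proteins))
      strsplit(proteins[[id]]$sequence, "")[[1]] else rep("X", length(s))
    line <- sprintf("%d\t%s\t%.6f", seq_along(s), res, s)
    if (!is.null(track$calls))
      line <- paste0(line, "\t", track$calls[[id]])
    writeLines(c(paste0(">", id), line), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Propensity-scale tables

#' Read an amino-acid propensity scale from TSV
#'
#' Expects a header line and columns `aa`, `value` and optionally
#' `significance`.
#'
#' @param path Path to the TSV file.
#' @param name Scale name; defaults to the file name without extension.
#' @return A [propensity_scale].
#' @export
read_scale <- function(path, name = NULL) {
  if (!file.exists(path)) stop_("scale file not found: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "value") %in% names(df)))
    stop_("%s: expected columns 'aa' and 'value'", path)
  if (anyDuplicated(df$aa)) stop_("%s: duplicated amino acid '%s'",
                                  path, df$aa[duplicated(df$aa)][1])
  vals <- stats::setNames(df$value, toupper(df$aa))
  sig <- if ("significance" %in% names(df))
    stats::setNames(df$significance, toupper(df$aa)) else NULL
  propensity_scale(name, vals, sig)
}

#' Write a propensity scale to TSV
#'
#' Round-trips with [read_scale()] up to float formatting.
#'
#' @param scale A [propensity_scale] (or [compute_scale()] result).
#' @param path Output path.
#' @param digits Number of significant digits written.
#' @export
write_scale <- function(scale, path, digits = 10) {
  stopifnot(inherits(scale, "propensity_scale"))
  df <- data.frame(aa = AA20, value = signif(scale$values, digits),
                   stringsAsFactors = FALSE)
  if (!is.null(scale$significance)) df$significance <- scale$significance
  if (!is.null(scale$p_value)) df$p_value <- signif(scale$p_value[AA20], digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
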