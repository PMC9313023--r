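# Region extraction, IDR categorisation and protein-level disorder classes.

# Maximal runs of the positive state in a 0/1/NA track; NA breaks a run.
positive_runs <- function(track, min_len = 1L) {
  pos <- !is.na(track) & track == 1L
  if (!any(pos)) return(data.frame(start = integer(), end = integer()))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract maximal annotated regions from a protein or protein set
#'
#' A region is a maximal run of consecutive residues in the positive state of
#' the requested track; unannotated residues break a run. IDRs are extracted
#' with the conventional minimum length of 10 consecutive disordered
#' residues; binding regions default to a minimum of 1.
#'
#' @param x An [annotated_protein] or a named list of them.
#' @param kind `"disorder"` or `"binding"`.
#' @param min_len Minimum region length; defaults to 10 for disorder and 1
#'   for binding.
#' @return A data frame with columns `protein_id`, `start`, `end` (1-based
#'   inclusive), `length`, `kind`, sorted by protein then start.
#' @export
extract_regions <- function(x, kind = c("disorder", "binding"), min_len = NULL) {
  kind <- match.arg(kind)
  if (is.null(min_len)) min_len <- if (kind == "disorder") 10L else 1L
  if (min_len < 1L) stop_("min_len must be >= 1")
  proteins <- if (inherits(x, "annotated_protein")) {
    stats::setNames(list(x), x$id)
  } else {
    assert_protein_list(x)
    x
  }
  rows <- lapply(proteins, function(p) {
    runs <- positive_runs(p[[kind]], min_len)
    if (!nrow(runs)) return(NULL)
    data.frame(protein_id = p$id, start = runs$start, end = runs$end,
               length = runs$end - runs$start + 1L, kind = kind,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else NULL
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Disorder content of a protein
#'
#' Fraction of residues annotated as disordered, counting all disordered
#' residues (including runs shorter than the IDR minimum length) over the
#' full sequence length.
#'
#' @param x An [annotated_protein] or a named list of them.
#' @return A single value, or a named numeric vector for a list.
#' @export
disorder_content <- function(x) {
  one <- function(p) {
    n <- nchar(p$sequence)
    if (n == 0L) stop_("protein '%s': zero-length sequence", p$id)
    sum(p$disorder == 1L, na.rm = TRUE) / n
  }
  if (inherits(x, "annotated_protein")) return(one(x))
  assert_protein_list(x)
  vapply(x, one, numeric(1))
}

#' Categorise IDRs by size, protein context and binding
#'
#' Each IDR (maximal disordered run of at least `idr_min_len` residues)
#' receives zero or more size categories and, independently, a binding flag:
#' \itemize{
#'   \item `fully_disordered`: the host protein has disorder content >=
#'     `full_content` (all IDRs of such proteins carry the flag);
#'   \item `short`: region length in `[idr_min_len, short_max]` and protein
#'     disorder content < `low_content`;
#'   \item `long`: region length >= `long_region_min` and protein disorder
#'     content in `[low_content, full_content]`;
#'   \item `binding`: the region overlaps an annotated binding region by at
#'     least one residue;
#'   \item `other`: none of the three size rules applies.
#' }
#'
#' @param proteins Named list of [annotated_protein].
#' @param idr_min_len Minimum IDR length (default 10).
#' @param short_max Maximum length of a short IDR (default 14, i.e. < 15).
#' @param long_region_min Minimum length of a long IDR (default 71, i.e. over
#'   70 residues).
#' @param low_content,full_content Disorder-content thresholds (defaults 0.3
#'   and 0.8).
#' @param binding_min_len Minimum binding-region length (default 1).
#' @return Data frame: one row per IDR with `protein_id`, `start`, `end`,
#'   `length`, `content` (host protein disorder content) and logical columns
#'   `fully_disordered`, `short`, `long`, `binding`, `other`.
#' @export
categorize_idrs <- function(proteins, idr_min_len = 10L, short_max = 14L,
                            long_region_min = 71L, low_content = 0.3,
                            full_content = 0.8, binding_min_len = 1L) {
  assert_protein_list(proteins)
  idrs <- extract_regions(proteins, "disorder", min_len = idr_min_len)
  bnd <- extract_regions(proteins, "binding", min_len = binding_min_len)
  content <- disorder_content(proteins)
  if (!nrow(idrs)) {
    idrs$content <- numeric()
    idrs$fully_disordered <- idrs$short <- idrs$long <-
      idrs$binding <- idrs$other <- logical()
    return(idrs)
  }
  idrs$content <- unname(content[idrs$protein_id])
  idrs$fully_disordered <- idrs$content >= full_content
  idrs$short <- idrs$length >= idr_min_len & idrs$length <= short_max &
    idrs$content < low_content
  idrs$long <- idrs$length >= long_region_min &
    idrs$content >= low_content & idrs$content <= full_content
  overlaps <- function(i) {
    b <- bnd[bnd$protein_id == idrs$protein_id[i], , drop = FALSE]
    any(b$start <= idrs$end[i] & b$end >= idrs$start[i])
  }
  idrs$binding <- if (nrow(bnd)) vapply(seq_len(nrow(idrs)), overlaps, logical(1))
                  else rep(FALSE, nrow(idrs))
  idrs$other <- !(idrs$fully_disordered | idrs$short | idrs$long)
  idrs
}

#' Assign each protein to one of six disorder classes
#'
#' Protein-level routing used for per-class predictor evaluation and the
#' meta-predictor. The six classes are mutually exclusive:
#' \enumerate{
#'   \item `fully_disordered`: disorder content >= `full_content`;
#'   \item `low_short`: content <= `low_content` with an IDR of
#'     `[idr_min_len, short_max]` residues;
#'   \item `low_binding_long`: content <= `low_content` with a binding IDR of
#'     at least `class_long_min` residues;
#'   \item `low_nonbinding_long`: content <= `low_content` with a non-binding
#'     IDR of at least `class_long_min` residues;
#'   \item `high_binding`: `low_content` < content < `full_content` with a
#'     binding IDR;
#'   \item `high_nonbinding`: `low_content` < content < `full_content`
#'     without binding IDRs.
#' }
#' Within the low-content classes the precedence is binding-long >
#' non-binding-long > short (configurable). Proteins matching no rule are
#' `"unassigned"`. Note the deliberate literal gap: a low-content protein
#' whose only IDRs have exactly `short_max + 1` residues (length 15 with the
#' defaults) triggers neither the short nor the long class rule.
#'
#' @inheritParams categorize_idrs
#' @param class_long_min Minimum IDR length for the "long" class rules
#'   (default 16, i.e. > 15); distinct from `long_region_min` used by the IDR
#'   *category* rules.
#' @param precedence Order in which the three low-content class rules are
#'   tried.
#' @return Data frame with columns `protein_id`, `class` (one of
#'   [IDP_CLASSES]) and `content`.
#' @export
classify_idps <- function(proteins, idr_min_len = 10L, short_max = 14L,
                          class_long_min = 16L, low_content = 0.3,
                          full_content = 0.8, binding_min_len = 1L,
                          precedence = c("low_binding_long",
                                         "low_nonbinding_long", "low_short")) {
  assert_protein_list(proteins)
  stopifnot(setequal(precedence,
                     c("low_binding_long", "low_nonbinding_long", "low_short")))
  idrs <- categorize_idrs(proteins, idr_min_len = idr_min_len,
                          short_max = short_max, low_content = low_content,
                          full_content = full_content,
                          binding_min_len = binding_min_len)
  content <- disorder_content(proteins)
  cls <- vapply(names(proteins), function(id) {
    cc <- content[[id]]
    if (cc >= full_content) return("fully_disordered")
    reg <- idrs[idrs$protein_id == id, , drop = FALSE]
    if (cc <= low_content) {
      hit <- c(
        low_binding_long = any(reg$length >= class_long_min & reg$binding),
        low_nonbinding_long = any(reg$length >= class_long_min & !reg$binding),
        low_short = any(reg$length <= short_max)
      )
      for (rule in precedence) if (hit[[rule]]) return(rule)
      return("unassigned")
    }
    # low_content < cc < full_content
    if (any(reg$binding)) "high_binding" else "high_nonbinding"
  }, character(1))
  data.frame(protein_id = names(proteins), class = unname(cls),
             content = unname(content[names(proteins)]),
             stringsAsFactors = FALSE)
}

#' Summarise IDRs per category
#'
#' Table of per-category counts and length statistics over the complete
#' dataset and the four IDR categories.
#'
#' @inheritParams categorize_idrs
#' @return Data frame with one row per protein set (`complete`,
#'   `fully_disordered`, `short`, `long`, `binding`) and columns
#'   `n_proteins`, `n_regions`, `n_residues`, `median_length`,
#'   `mean_length` (1 decimal). Categories with no regions are omitted.
#' @export
region_summary <- function(proteins, ...) {
  if (length(proteins) == 0)
    return(data.frame(set = character(), n_proteins = integer(),
                      n_regions = integer(), n_residues = integer(),
                      median_length = numeric(), mean_length = numeric(),
                      stringsAsFactors = FALSE))
  idrs <- categorize_idrs(proteins, ...)
  one <- function(set, mask) {
    sub <- idrs[mask, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(set = set,
               n_proteins = length(unique(sub$protein_id)),
               n_regions = nrow(sub),
               n_residues = sum(sub$length),
               median_length = stats::median(sub$length),
               mean_length = round(mean(sub$length), 1),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("complete", rep(TRUE, nrow(idrs))),
               one("fully_disordered", idrs$fully_disordered),
               one("short", idrs$short),
               one("long", idrs$long),
               one("binding", idrs$binding))
  if (is.null(out)) out <- region_summary(list())
  rownames(out) <- NULL
  out
}
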