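# Shared fixtures and independent brute-force oracles.

# Protein from compact label strings: "1"/"0"/"-" for the tracks.
make_protein <- function(id, seq, dis, bind = NULL) {
  to_track <- function(s) {
    ch <- strsplit(s, "")[[1]]
    tr <- rep(NA_integer_, length(ch))
    tr[ch == "1"] <- 1L
    tr[ch == "0"] <- 0L
    tr
  }
  n <- nchar(seq)
  annotated_protein(id, seq, disorder = to_track(dis),
                    binding = if (is.null(bind)) rep(0L, n) else to_track(bind))
}

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Exhaustive segment scan: every (start, end) window that is all-positive,
# maximal and long enough.
oracle_runs <- function(track, min_len) {
  n <- length(track)
  pos <- !is.na(track) & track == 1L
  out <- list()
  for (s in seq_len(n)) for (e in s:n) {
    if (!all(pos[s:e])) next
    if (s > 1 && pos[s - 1]) next
    if (e < n && pos[e + 1]) next
    if (e - s + 1 >= min_len) out[[length(out) + 1]] <- c(s, e)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# O(n^2) concordant/discordant pair counting, tie-corrected (tau-b).
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exhaustive positive x negative pair counting AUC (ties count 1/2).
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}
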