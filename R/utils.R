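# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls have no RNG side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a run seed; kept well below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 20000000L) * 100L + as.integer(offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_protein_list <- function(x) {
  is.list(x) && length(x) > 0 && all(vapply(x, inherits, logical(1), "annotated_protein"))
}

assert_protein_list <- function(proteins) {
  if (!is_protein_list(proteins))
    stop_("expected a non-empty list of 'annotated_protein' objects")
  ids <- vapply(proteins, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_("duplicate protein id: %s", ids[duplicated(ids)][1])
  invisible(ids)
}
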