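#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not perturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed from a base seed and an index
#'
#' All randomness flows through one seeded hierarchy (cohort seed ->
#' per-lesion substreams) so adding a lesion does not perturb the others.
#' Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 7919 + 12345) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
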