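#' @useDynLib psexplore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rcauchy median sd
#' @importFrom utils write.csv
NULL

# RNG stream management.
#
# All randomness is organised as L'Ecuyer-CMRG streams (parallel::nextRNGStream):
# one "engine" stream drives selection / variation / tie-breaks, and every
# evaluation receives its own independent stream, with one substream per
# replicate.  This realises a (masterSeed, evalIndex, replicateIndex) stream
# derivation: sequential runs are bit-reproducible, and evaluations could be
# dispatched to workers without changing any single evaluation's result.

rng_master <- function(master_seed) {
  old_kind <- RNGkind()
  on.exit(do.call(RNGkind, as.list(old_kind)), add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(master_seed))
  seed <- get(".Random.seed", envir = globalenv())
  list(engine = seed, eval_base = parallel::nextRNGStream(seed))
}

# Run fn() with .Random.seed set to `state`; return list(value, state) where
# state is the advanced seed, so the caller can thread the stream explicitly.
with_rng_state <- function(state, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", state, envir = globalenv())
  value <- fn()
  new_state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  list(value = value, state = new_state)
}

# Independent substreams of `state` (replicate streams of one evaluation).
rng_substreams <- function(state, n) {
  out <- vector("list", n)
  s <- state
  for (i in seq_len(n)) {
    s <- parallel::nextRNGSubStream(s)
    out[[i]] <- s
  }
  out
}
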