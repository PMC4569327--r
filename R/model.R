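#' Model-plugin contract
#'
#' A simulator is plugged into the exploration engine as a function from a
#' parameter vector to a raw pattern vector.  The function must consume
#' randomness only through R's RNG (`runif()`, `rnorm()`, ...): the engine
#' sets an independent replicate stream before every call, so the same
#' parameter values under the same stream always reproduce the same pattern.
#'
#' @param name model name (used by the registry and the CLI).
#' @param k number of model parameters (genome length).
#' @param m number of pattern dimensions.
#' @param fn `function(values)` returning a numeric pattern of length `m`.
#' @param bounds default [bounds()] for the free parameters (optional).
#' @param discretisation default [discretisation()] of the pattern space
#'   (optional).
#' @return An object of class `pse_model`.
#' @export
model_plugin <- function(name, k, m, fn, bounds = NULL, discretisation = NULL) {
  stopifnot(is.function(fn), k >= 1, m >= 1)
  structure(list(name = name, k = as.integer(k), m = as.integer(m), fn = fn,
                 bounds = bounds, discretisation = discretisation),
            class = "pse_model")
}

#' @export
print.pse_model <- function(x, ...) {
  cat("Model plugin '", x$name, "': ", x$k, " parameters -> ",
      x$m, "-dimensional pattern\n", sep = "")
  invisible(x)
}

.model_registry <- new.env(parent = emptyenv())

#' Register / fetch model plugins by name
#'
#' @param model a [model_plugin()].
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "pse_model"))
  .model_registry[[model$name]] <- model
  invisible(model)
}

#' @rdname register_model
#' @param name registered model name.
#' @export
get_model <- function(name) {
  m <- .model_registry[[name]]
  if (is.null(m))
    stop("unknown model '", name, "'; registered: ",
         paste(ls(.model_registry), collapse = ", "))
  m
}

#' Evaluate a genome through a model
#'
#' Runs the model once per replicate, each replicate under its own RNG
#' substream of `eval_stream`.  Every replicate's raw pattern is clamped to
#' the discretisation bounds *before* aggregation, then the phenotype is the
#' per-dimension median over replicates (mean of the two middle values for an
#' even count), and the phenotype is located in its archive cell.
#'
#' @param g a [genome()].
#' @param model a [model_plugin()].
#' @param replications number of replicate simulations (>= 1).
#' @param d the pattern-space [discretisation()].
#' @param eval_stream an L'Ecuyer-CMRG seed state for this evaluation.
#' @return list with `individual` (genome, phenotype, cell) and `raw`
#'   (replications x M matrix of clamped replicate patterns).
#' @export
evaluate_individual <- function(g, model, replications, d, eval_stream) {
  stopifnot(replications >= 1)
  streams <- rng_substreams(eval_stream, replications)
  raw <- matrix(NA_real_, nrow = replications, ncol = d$m)
  for (r in seq_len(replications)) {
    res <- tryCatch(
      with_rng_state(streams[[r]], function() model$fn(g$values)),
      error = function(e)
        stop("model '", model$name, "' failed at genome (",
             paste(signif(g$values, 6), collapse = ", "),
             "), replicate ", r, ": ", conditionMessage(e), call. = FALSE))
    pat <- res$value
    if (length(pat) != d$m)
      stop("model '", model$name, "' returned a pattern of length ",
           length(pat), ", expected ", d$m)
    raw[r, ] <- clamp_pattern(as.numeric(pat), d)
  }
  phen <- apply(raw, 2, median)
  loc <- discretise_phenotype(phen, d)
  list(individual = list(genome = g, phenotype = loc$phenotype,
                         cell = loc$cell),
       raw = raw)
}
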