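#' Read an exploration configuration from a YAML file
#'
#' The file mirrors [pse_config()]: top-level keys `model` (a registered
#' model name), `mu`, `max_evaluations`, `replications`, `reeval_prob`,
#' `sbx_eta`, `master_seed`, `lambda`, `n_islands`, `evals_per_island`,
#' `island_mu`, and optional blocks `bounds:` (`lower:`, `upper:` lists) and
#' `discretisation:` (`step:`, `lower_clamp:`, `upper_clamp:`) overriding
#' the model's defaults.  `overrides` (typically CLI flags) take precedence
#' over file values.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return list with `config` (a [pse_config()]) and `model` (the plugin).
#' @export
read_pse_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  if (is.null(raw$model)) stop("config must name a registered 'model'")
  model <- get_model(raw$model)
  b <- if (!is.null(raw$bounds)) {
    bounds(unlist(raw$bounds$lower), unlist(raw$bounds$upper))
  } else model$bounds
  if (is.null(b)) stop("no bounds in config and model has no defaults")
  d <- if (!is.null(raw$discretisation)) {
    dc <- raw$discretisation
    discretisation(unlist(dc$step),
                   if (!is.null(dc$lower_clamp)) unlist(dc$lower_clamp),
                   if (!is.null(dc$upper_clamp)) unlist(dc$upper_clamp))
  } else model$discretisation
  if (is.null(d)) stop("no discretisation in config and model has no defaults")
  take <- function(name, default) if (is.null(raw[[name]])) default
          else raw[[name]]
  cfg <- pse_config(
    bounds = b, discretisation = d,
    mu = take("mu", 100L),
    max_evaluations = take("max_evaluations", 1000L),
    replications = take("replications", 1L),
    reeval_prob = take("reeval_prob", 0.01),
    sbx_eta = take("sbx_eta", 2),
    scale_init = take("scale_init", 0.1),
    master_seed = take("master_seed", 42L),
    lambda = take("lambda", 1L),
    n_islands = take("n_islands", 1L),
    evals_per_island = raw$evals_per_island,
    island_mu = raw$island_mu)
  list(config = cfg, model = model)
}
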