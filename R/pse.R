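#' Configuration of a Pattern Space Exploration run
#'
#' @param bounds parameter-space [bounds()].
#' @param discretisation pattern-space [discretisation()].
#' @param mu initial population size (>= 2 for a meaningful run; >= 1
#'   accepted).
#' @param max_evaluations total evaluation budget, including the `mu` initial
#'   evaluations.
#' @param replications replicate simulations per evaluation.
#' @param reeval_prob probability, at each steady-state iteration, of
#'   re-evaluating a selected individual's genome unchanged (all replicates
#'   rerun) instead of breeding a new one.
#' @param sbx_eta SBX distribution index.
#' @param scale_init initial self-adaptive mutation scale per gene.
#' @param master_seed integer seed from which every stream of the run is
#'   derived.
#' @param lambda offspring bred from the same population snapshot between
#'   elitism passes; 1 (default) is the exact steady-state (mu+1) loop.
#' @param n_islands,evals_per_island,island_mu island-model settings for
#'   [run_islands()]: number of islands per round, evaluation budget per
#'   island, and the size of the population subset seeding each island.
#' @return An object of class `pse_config`.
#' @export
pse_config <- function(bounds, discretisation, mu, max_evaluations,
                       replications = 1L, reeval_prob = 0.01, sbx_eta = 2,
                       scale_init = 0.1, master_seed = 42L, lambda = 1L,
                       n_islands = 1L, evals_per_island = NULL,
                       island_mu = NULL) {
  stopifnot(inherits(bounds, "pse_bounds"),
            inherits(discretisation, "pse_discretisation"),
            mu >= 1, max_evaluations >= mu, replications >= 1,
            reeval_prob >= 0, reeval_prob <= 1, sbx_eta > 0,
            lambda >= 1, n_islands >= 1)
  structure(list(bounds = bounds, discretisation = discretisation,
                 mu = as.integer(mu),
                 max_evaluations = as.integer(max_evaluations),
                 replications = as.integer(replications),
                 reeval_prob = reeval_prob, sbx_eta = sbx_eta,
                 scale_init = scale_init,
                 master_seed = as.integer(master_seed),
                 lambda = as.integer(lambda),
                 n_islands = as.integer(n_islands),
                 evals_per_island = evals_per_island,
                 island_mu = island_mu),
            class = "pse_config")
}

#' @export
print.pse_config <- function(x, ...) {
  cat("PSE configuration: mu =", x$mu, ", budget =", x$max_evaluations,
      "evaluations,", x$replications, "replications, reeval_prob =",
      x$reeval_prob, "\n")
  invisible(x)
}

# Mutable evolution state: population (list of individuals), hit-map archive,
# evaluation counter, trace, and the two RNG streams.
new_state <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$population <- list()
  e$hitmap <- hitmap()
  e$eval_count <- 0L
  e$trace <- vector("list", 256L)
  e$trace_n <- 0L
  rng <- rng_master(cfg$master_seed)
  e$engine_rng <- rng$engine
  e$eval_rng <- rng$eval_base
  class(e) <- "pse_state"
  e
}

#' @export
print.pse_state <- function(x, ...) {
  cat("PSE state:", x$eval_count, "evaluations,",
      volume_discovered(x$hitmap), "cells discovered, population size",
      length(x$population), "\n")
  invisible(x)
}

append_record <- function(state, rec) {
  n <- state$trace_n + 1L
  if (n > length(state$trace))
    state$trace <- c(state$trace, vector("list", length(state$trace)))
  state$trace[[n]] <- rec
  state$trace_n <- n
}

# Evaluate one genome under the next evaluation stream, record the hit and
# append a trace row.  Returns the evaluated individual.
do_evaluation <- function(state, g, model, cfg) {
  state$eval_rng <- parallel::nextRNGStream(state$eval_rng)
  ev <- evaluate_individual(g, model, cfg$replications, cfg$discretisation,
                            state$eval_rng)
  record_hit(state$hitmap, ev$individual$cell)
  state$eval_count <- state$eval_count + 1L
  append_record(state, list(eval_index = state$eval_count,
                            values = g$values,
                            raw = ev$raw,
                            phenotype = ev$individual$phenotype,
                            cell = ev$individual$cell))
  ev$individual
}

# Run fn() under the engine RNG stream, threading its state.
with_engine_rng <- function(state, fn) {
  res <- with_rng_state(state$engine_rng, fn)
  state$engine_rng <- res$state
  res$value
}

#' Binary tournament selection by phenotype rarity
#'
#' Two members are drawn uniformly at random (without replacement when the
#' population has at least two); the one whose archive cell has the lower hit
#' count — the rarer phenotype — wins.  Equal counts are broken uniformly at
#' random.  Uses the current RNG stream.
#'
#' @param pop list of evaluated individuals.
#' @param h the [hitmap()] archive.
#' @return The selected individual.
#' @export
tournament_select <- function(pop, h) {
  n <- length(pop)
  if (n == 0) stop("cannot select from an empty population")
  if (n == 1) return(pop[[1]])
  idx <- sample.int(n, 2L, replace = FALSE)
  c1 <- hit_count(h, pop[[idx[1]]]$cell)
  c2 <- hit_count(h, pop[[idx[2]]]$cell)
  if (c1 < c2) pop[[idx[1]]]
  else if (c2 < c1) pop[[idx[2]]]
  else pop[[idx[1 + (runif(1) < 0.5)]]]
}

#' One-per-cell elitism filter
#'
#' Groups individuals by archive cell and keeps exactly one per occupied
#' cell, chosen uniformly at random among the cell's candidates (current RNG
#' stream).  The population grows whenever a new cell appears: nobody is
#' displaced by a member of another cell.
#'
#' @param pop list of evaluated individuals (parents and offspring).
#' @return The filtered population (list).
#' @export
elitism_filter <- function(pop) {
  if (length(pop) == 0) return(list())
  keys <- vapply(pop, function(ind) cell_key(ind$cell), character(1))
  groups <- split(seq_along(pop), keys)
  keep <- vapply(groups, function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  pop[sort(keep)]
}

#' Initialise the evolution state
#'
#' Draws `mu` genomes uniformly in the bounds, evaluates them (recording
#' hits and trace rows) and applies the elitism filter.
#'
#' @param cfg a [pse_config()].
#' @param model a [model_plugin()].
#' @return A `pse_state`.
#' @export
initialise_population <- function(cfg, model) {
  stopifnot(model$k == cfg$bounds$k)
  state <- new_state(cfg)
  genomes <- with_engine_rng(state, function()
    lapply(seq_len(cfg$mu), function(i)
      random_genome(cfg$bounds, cfg$scale_init)))
  evaluated <- lapply(genomes, function(g) do_evaluation(state, g, model, cfg))
  state$population <- with_engine_rng(state, function()
    elitism_filter(evaluated))
  state
}

#' One steady-state PSE iteration
#'
#' With probability `reeval_prob` a tournament-selected parent's genome is
#' re-evaluated unchanged (all replicates rerun — sharpening the phenotype
#' estimate of noisy individuals); otherwise two binary tournaments pick the
#' parents, SBX crossover and the adaptive Cauchy mutation produce one
#' offspring, and it is evaluated.  The hit map is updated at evaluation
#' time, then the elitism filter runs over the population plus the new
#' individual.  Exactly one evaluation is consumed.
#'
#' @param state a `pse_state` from [initialise_population()].
#' @inheritParams initialise_population
#' @return `state`, invisibly (updated in place).
#' @export
pse_step <- function(state, cfg, model) {
  g <- with_engine_rng(state, function() {
    if (runif(1) < cfg$reeval_prob) {
      tournament_select(state$population, state$hitmap)$genome
    } else {
      p1 <- tournament_select(state$population, state$hitmap)
      p2 <- tournament_select(state$population, state$hitmap)
      child <- sbx_crossover(p1$genome, p2$genome, cfg$bounds, cfg$sbx_eta)
      adaptive_cauchy_mutate(child, cfg$bounds)
    }
  })
  ind <- do_evaluation(state, g, model, cfg)
  state$population <- with_engine_rng(state, function()
    elitism_filter(c(state$population, list(ind))))
  invisible(state)
}

#' Run a sequential Pattern Space Exploration
#'
#' Initialises the population and iterates [pse_step()] until the evaluation
#' budget is spent.  With `lambda > 1`, `lambda` offspring are bred from the
#' same population snapshot before each elitism pass (the generational
#' reading of the evaluation pool); `lambda = 1` is the pure steady-state
#' loop.  A run is fully reproducible from `master_seed`.
#'
#' @inheritParams initialise_population
#' @return The final `pse_state`; retrieve the evaluation trace with
#'   [pse_trace()].
#' @examples
#' staircase <- model_plugin("staircase", k = 2, m = 1,
#'   fn = function(v) floor(3 * v[1]) + 3 * floor(3 * v[2]))
#' cfg <- pse_config(bounds(c(0, 0), c(1, 1)), discretisation(1),
#'                   mu = 10, max_evaluations = 300, master_seed = 1)
#' st <- run_pse(cfg, staircase)
#' volume_discovered(st$hitmap)  # 9 reachable cells
#' @export
run_pse <- function(cfg, model) {
  state <- initialise_population(cfg, model)
  while (state$eval_count < cfg$max_evaluations) {
    if (cfg$lambda == 1L) {
      pse_step(state, cfg, model)
    } else {
      n_off <- min(cfg$lambda, cfg$max_evaluations - state$eval_count)
      offspring <- vector("list", n_off)
      for (i in seq_len(n_off)) {
        g <- with_engine_rng(state, function() {
          if (runif(1) < cfg$reeval_prob) {
            tournament_select(state$population, state$hitmap)$genome
          } else {
            p1 <- tournament_select(state$population, state$hitmap)
            p2 <- tournament_select(state$population, state$hitmap)
            child <- sbx_crossover(p1$genome, p2$genome, cfg$bounds,
                                   cfg$sbx_eta)
            adaptive_cauchy_mutate(child, cfg$bounds)
          }
        })
        offspring[[i]] <- do_evaluation(state, g, model, cfg)
      }
      state$population <- with_engine_rng(state, function()
        elitism_filter(c(state$population, offspring)))
    }
  }
  state
}

#' Run the island-model Pattern Space Exploration
#'
#' A global population and hit map are initialised as in the sequential run.
#' Each island is seeded with a uniform random subset of the global
#' population and a copy of the global hit map, runs the steady-state (mu+1)
#' loop for `evals_per_island` evaluations, and on completion its hit
#' increments are added to the global map and its population merged through
#' the elitism filter.  Rounds of `n_islands` islands repeat until the global
#' budget is reached.  Islands are executed sequentially here; the merge
#' semantics are what the distributed deployment would preserve.
#'
#' @inheritParams initialise_population
#' @return The final global `pse_state`.
#' @export
run_islands <- function(cfg, model) {
  state <- initialise_population(cfg, model)
  epi <- cfg$evals_per_island
  if (is.null(epi)) epi <- max(1L, (cfg$max_evaluations - cfg$mu) %/% 10L)
  while (state$eval_count < cfg$max_evaluations) {
    for (isl in seq_len(cfg$n_islands)) {
      if (state$eval_count >= cfg$max_evaluations) break
      budget <- min(epi, cfg$max_evaluations - state$eval_count)
      imu <- cfg$island_mu
      if (is.null(imu)) imu <- length(state$population)
      n_seed <- min(imu, length(state$population))
      island_pop <- if (n_seed == length(state$population)) {
        state$population  # whole population: no subset draw needed
      } else {
        seed_ix <- with_engine_rng(state, function()
          sample.int(length(state$population), n_seed))
        state$population[seed_ix]
      }
      island_hits <- hitmap_copy(state$hitmap)
      for (it in seq_len(budget)) {
        g <- with_engine_rng(state, function() {
          if (runif(1) < cfg$reeval_prob) {
            tournament_select(island_pop, island_hits)$genome
          } else {
            p1 <- tournament_select(island_pop, island_hits)
            p2 <- tournament_select(island_pop, island_hits)
            child <- sbx_crossover(p1$genome, p2$genome, cfg$bounds,
                                   cfg$sbx_eta)
            adaptive_cauchy_mutate(child, cfg$bounds)
          }
        })
        # evaluation is recorded directly in the global state (trace and
        # global hit map); the island also records it locally for selection
        ind <- do_evaluation(state, g, model, cfg)
        record_hit(island_hits, ind$cell)
        island_pop <- with_engine_rng(state, function()
          elitism_filter(c(island_pop, list(ind))))
      }
      state$population <- with_engine_rng(state, function()
        elitism_filter(c(state$population, island_pop)))
    }
  }
  state
}

#' Evaluation trace of a run
#'
#' One row per evaluation, in order: the genome values (`g1..gK`), phenotype
#' (`p1..pM`), archive cell coordinates (`c1..cM`) and the cumulative number
#' of distinct cells discovered (`volume`).  Replicate-level raw patterns are
#' kept in the state's `trace` list.
#'
#' @param state a `pse_state` (or the trace-holding result of
#'   [evaluate_design()]).
#' @return A data.frame.
#' @export
pse_trace <- function(state) {
  recs <- state$trace[seq_len(state$trace_n)]
  if (length(recs) == 0)
    return(data.frame(eval_index = integer(0)))
  k <- length(recs[[1]]$values)
  m <- length(recs[[1]]$phenotype)
  df <- data.frame(eval_index = vapply(recs, `[[`, integer(1), "eval_index"))
  gv <- matrix(unlist(lapply(recs, `[[`, "values")), ncol = k, byrow = TRUE)
  pv <- matrix(unlist(lapply(recs, `[[`, "phenotype")), ncol = m,
               byrow = TRUE)
  cv <- matrix(unlist(lapply(recs, `[[`, "cell")), ncol = m, byrow = TRUE)
  colnames(gv) <- paste0("g", seq_len(k))
  colnames(pv) <- paste0("p", seq_len(m))
  colnames(cv) <- paste0("c", seq_len(m))
  keys <- apply(cv, 1, paste, collapse = ",")
  df <- cbind(df, gv, pv, cv)
  df$volume <- cumsum(!duplicated(keys))
  df
}
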